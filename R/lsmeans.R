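# Least-squares (adjusted) means and pairwise contrasts.  The adjusted mean
# of a focus-factor level is the model prediction averaged with equal
# weights over the levels of the other factors in the fixed part.

#' Least-squares means and pairwise contrasts
#'
#' @param object a fitted model: an `lm` (per-location marker analyses) or
#'   a `met_fit` from [reml_fit()].
#' @param focus name of the factor whose adjusted means are wanted.
#' @param ... unused.
#' @return A `met_lsmeans` list with `means` (level, n, lsmean, se) and
#'   `contrasts` (all pairwise differences with standard errors and
#'   p-values; t-based for `lm`, normal-based for mixed fits).
#' @export
ls_means <- function(object, focus, ...) UseMethod("ls_means")

#' @export
ls_means.lm <- function(object, focus, ...) {
  trms <- delete.response(terms(object))
  mf <- model.frame(object)
  xlev <- object$xlevels
  if (!focus %in% names(xlev))
    stop_metgxe("focus factor '", focus, "' not in the fixed part")
  vars <- attr(trms, "term.labels")
  vars <- unique(unlist(strsplit(vars, ":", fixed = TRUE)))
  grid_parts <- list()
  for (v in vars) {
    grid_parts[[v]] <- if (v %in% names(xlev)) xlev[[v]]
                       else mean(mf[[v]])
  }
  grid <- expand.grid(grid_parts, stringsAsFactors = TRUE)
  for (v in names(xlev)) grid[[v]] <- factor(grid[[v]], levels = xlev[[v]])
  X <- model.matrix(trms, grid, contrasts.arg = object$contrasts)
  beta <- coef(object)
  keep <- !is.na(beta)
  if (!all(keep))
    warning("aliased coefficient(s) dropped from lsmeans: ",
            paste(names(beta)[!keep], collapse = ", "), call. = FALSE)
  X <- X[, keep, drop = FALSE]
  beta <- beta[keep]
  V <- vcov(object)
  lsmean_rows(grid, X, beta, V, focus, mf,
              df = object$df.residual)
}

#' @export
ls_means.met_fit <- function(object, focus, ...) {
  design <- object$design
  xlev <- design$xlevels
  if (!focus %in% names(xlev))
    stop_metgxe("focus factor '", focus, "' not in the fixed part")
  vars <- unique(unlist(strsplit(design$term_labels, ":", fixed = TRUE)))
  grid_parts <- list()
  for (v in vars) {
    grid_parts[[v]] <- if (v %in% names(xlev)) xlev[[v]]
                       else mean(design$data[[v]])
  }
  grid <- expand.grid(grid_parts, stringsAsFactors = TRUE)
  for (v in names(xlev)) grid[[v]] <- factor(grid[[v]], levels = xlev[[v]])
  Xg <- model.matrix(design$terms, grid, contrasts.arg = design$contrasts)
  Xg <- Xg[, colnames(design$X), drop = FALSE]
  lsmean_rows(grid, Xg, object$beta, object$cov_beta, focus, design$data,
              df = Inf)
}

lsmean_rows <- function(grid, X, beta, V, focus, data, df) {
  levels_f <- levels(grid[[focus]])
  observed <- levels_f %in% unique(as.character(data[[focus]]))
  if (any(!observed))
    warning("empty level(s) of ", focus, " omitted: ",
            paste(levels_f[!observed], collapse = ", "), call. = FALSE)
  levels_f <- levels_f[observed]
  L <- t(vapply(levels_f, function(a)
    colMeans(X[grid[[focus]] == a, , drop = FALSE]), numeric(ncol(X))))
  est <- drop(L %*% beta)
  se <- sqrt(pmax(0, rowSums((L %*% V) * L)))
  counts <- table(data[[focus]])[levels_f]
  means <- data.frame(level = levels_f, n = as.integer(counts),
                      lsmean = est, se = se, row.names = NULL)
  pairs <- which(upper.tri(diag(length(levels_f))), arr.ind = TRUE)
  contrasts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    l <- L[i, ] - L[j, ]
    d <- sum(l * beta)
    s <- sqrt(max(0, sum((l %*% V) * l)))
    stat <- if (s > 0) d / s else NA_real_
    p <- if (is.na(stat)) NA_real_
         else if (is.finite(df)) 2 * pt(-abs(stat), df)
         else 2 * pnorm(-abs(stat))
    data.frame(a = levels_f[i], b = levels_f[j], diff = d, se = s,
               statistic = stat, p = p)
  }))
  rownames(contrasts) <- NULL
  structure(list(means = means, contrasts = contrasts, focus = focus,
                 df = df),
            class = "met_lsmeans")
}

#' @export
print.met_lsmeans <- function(x, ...) {
  cat("Least-squares means for", x$focus, "\n")
  print(x$means, digits = 4)
  cat("pairwise contrasts (a - b):\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Pairwise differences of class means
#'
#' Computes all pairwise differences among a set of per-class adjusted
#' means, e.g. published marker-class least-squares means.  The difference
#' for a pair is `means[a] - means[b]` with `a` preceding `b` in the input
#' order.
#'
#' @param means named numeric vector of class means.
#' @return data frame with columns `a`, `b`, `diff`.
#' @seealso [class_contrast()] for one directed difference.
#' @export
pairwise_contrasts <- function(means) {
  if (is.null(names(means)) || length(means) < 2)
    stop_metgxe("means must be a named vector of length >= 2")
  pairs <- which(upper.tri(diag(length(means))), arr.ind = TRUE)
  out <- data.frame(a = names(means)[pairs[, 1]],
                    b = names(means)[pairs[, 2]],
                    diff = means[pairs[, 1]] - means[pairs[, 2]])
  rownames(out) <- NULL
  out
}

#' Directed difference between two class means
#'
#' @param means named numeric vector of class means.
#' @param a,b class names; the result is `means[a] - means[b]`.
#' @return numeric scalar.
#' @export
class_contrast <- function(means, a, b) {
  if (!all(c(a, b) %in% names(means)))
    stop_metgxe("class(es) not found in means: ",
                paste(setdiff(c(a, b), names(means)), collapse = ", "))
  unname(means[a] - means[b])
}
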