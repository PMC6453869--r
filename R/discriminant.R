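#' Standardize descriptor columns
#'
#' Centres each descriptor column to mean 0 and scales it to unit
#' standard deviation (n - 1 denominator). Constant columns are an
#' error, since they carry no discriminative information and make the
#' scaling undefined.
#'
#' @param table a `descriptor_table`, data frame or numeric matrix
#'   (e.g. two class tables pooled with `rbind`).
#' @param columns columns to standardize; defaults to the descriptor
#'   columns present in the input.
#' @return Numeric matrix with attributes `center` and `scale`.
#' @export
standardize <- function(table, columns = NULL) {
  if (is.matrix(table)) {
    x <- table
  } else {
    if (is.null(columns)) columns <- intersect(descriptor_names(), names(table))
    x <- as.matrix(table[, columns, drop = FALSE])
  }
  if (nrow(x) < 2L) stop("standardization needs at least 2 rows")
  if (anyNA(x)) stop("descriptor matrix contains missing values")
  ctr <- colMeans(x)
  sds <- apply(x, 2L, sd)
  bad <- which(sds < .Machine$double.eps^0.5 * pmax(abs(ctr), 1))
  if (length(bad) > 0L)
    stop("constant descriptor column(s): ", paste(colnames(x)[bad], collapse = ", "))
  z <- sweep(sweep(x, 2L, ctr), 2L, sds, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}

#' Two-class linear discriminant ranking of shape descriptors
#'
#' Fisher's two-class linear discriminant on jointly standardized
#' descriptors: the discriminant direction is
#' `w = Sw^-1 (mean_a - mean_b)` with `Sw` the pooled within-class
#' covariance (equal priors). Because predictors are standardized, the
#' absolute value of each coefficient measures how strongly that
#' descriptor contributes to the separation between the two classes, and
#' `ranking` orders descriptors by decreasing `|weight|`.
#'
#' A small ridge term (`ridge * trace(Sw)` added to the diagonal)
#' stabilizes near-singular pooled covariances.
#'
#' @param table_a,table_b `descriptor_table`s (or data frames) for the
#'   two classes, each with >= 2 rows.
#' @param descriptors descriptor columns to use; defaults to the
#'   canonical descriptors present in both tables.
#' @param ridge relative ridge regularization (default 1e-6).
#' @return An object of class `discriminant_result`: list with `weights`
#'   (named, standardized scale), `ranking` (descriptor names by
#'   decreasing `|weight|`), `class_means` (standardized, per class),
#'   `separation` (standardized distance between projected class means)
#'   and `n` (per-class row counts).
#' @examples
#' pops <- generate_two_class_shapes(
#'   micromass_scene_spec(area_range = c(250, 350), n_objects = 5),
#'   micromass_scene_spec(area_range = c(700, 900), n_objects = 5),
#'   n_per_class = 30, seed = 1)
#' fit <- fit_discriminant(pops$a, pops$b)
#' fit$ranking[1]
#' @export
fit_discriminant <- function(table_a, table_b, descriptors = NULL, ridge = 1e-6) {
  if (is.null(descriptors))
    descriptors <- intersect(intersect(descriptor_names(), names(table_a)),
                             names(table_b))
  na <- nrow(table_a); nb <- nrow(table_b)
  if (is.null(na) || is.null(nb) || na < 2L || nb < 2L)
    stop("each class needs at least 2 rows")
  xa <- as.matrix(table_a[, descriptors, drop = FALSE])
  xb <- as.matrix(table_b[, descriptors, drop = FALSE])
  z <- standardize(rbind(xa, xb))
  za <- z[seq_len(na), , drop = FALSE]
  zb <- z[na + seq_len(nb), , drop = FALSE]
  ma <- colMeans(za); mb <- colMeans(zb)
  sw <- ((na - 1) * cov(za) + (nb - 1) * cov(zb)) / (na + nb - 2)
  swr <- sw + diag(ridge * sum(diag(sw)), ncol(sw))
  w <- tryCatch(solve(swr, ma - mb),
                error = function(e)
                  stop("pooled within-class covariance is singular; ",
                       "increase the ridge term or drop collinear descriptors"))
  w <- drop(w)
  names(w) <- descriptors
  sep <- abs(sum(w * (ma - mb))) / sqrt(drop(t(w) %*% sw %*% w))
  structure(list(weights = w,
                 ranking = descriptors[order(abs(w), decreasing = TRUE)],
                 class_means = rbind(a = ma, b = mb),
                 separation = sep,
                 n = c(a = na, b = nb),
                 ridge = ridge),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("Two-class linear discriminant over", length(x$weights), "descriptors\n")
  cat("n =", x$n["a"], "/", x$n["b"],
      " separation =", signif(x$separation, 4), "\n")
  cat("ranking (by |weight|):\n")
  w <- x$weights[x$ranking]
  for (i in seq_along(w))
    cat(sprintf("  %2d. %-16s %+ .4f\n", i, names(w)[i], w[i]))
  invisible(x)
}

#' Write a discriminant result as JSON
#' @param fit a `discriminant_result`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_discriminant_json <- function(fit, path) {
  jsonlite::write_json(
    list(weights = as.list(fit$weights),
         ranking = fit$ranking,
         class_means = list(a = as.list(fit$class_means["a", ]),
                            b = as.list(fit$class_means["b", ])),
         separation = fit$separation,
         n = as.list(fit$n)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
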