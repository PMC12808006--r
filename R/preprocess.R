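#' Standardize clustering columns to zero mean and unit variance
#'
#' All clustering variables — binary condition flags included — are
#' standardized with the sample standard deviation (divisor n - 1).
#' Sociodemographics are not clustering inputs and are untouched.
#'
#' @param x Numeric matrix (persons x variables).
#' @return List with `matrix` (standardized), `col_means`, `col_sds`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- which(sdv == 0 | is.na(sdv))
  if (length(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s) cannot be standardized: ",
         paste(nm, collapse = ", "))
  }
  list(matrix = sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/"),
       col_means = mu, col_sds = sdv)
}

#' Domain-balancing weight for the utilization block
#'
#' With p_c standardized condition columns and p_u standardized utilization
#' columns, the expected squared Euclidean distance between two independent
#' persons is 2*p_c within the condition block and 2*p_u within the
#' utilization block. Multiplying the utilization block by w = sqrt(p_c/p_u)
#' equalizes the two expected contributions; with the full schema this is
#' sqrt(33/7).
#'
#' @param p_c Number of condition columns (>= 1).
#' @param p_u Number of utilization columns (>= 1).
#' @return The scalar weight sqrt(p_c / p_u).
#' @export
compute_domain_weight <- function(p_c, p_u) {
  if (length(p_c) != 1L || length(p_u) != 1L || p_c < 1 || p_u < 1) {
    stop("p_c and p_u must be positive scalars")
  }
  sqrt(p_c / p_u)
}

#' Apply the domain weight to the utilization block
#'
#' @param m Standardized matrix with `p_c` condition columns followed by
#'   `p_u` utilization columns.
#' @param weight Positive scalar multiplier for the utilization columns.
#' @param p_c,p_u Block sizes; `p_c + p_u` must equal `ncol(m)`.
#' @param col_means,col_sds Optional standardization parameters carried on
#'   the returned design.
#' @return Object of class `weighted_design`: fields `matrix` (weighted),
#'   `col_means`, `col_sds`, `weight`, `p_c`, `p_u`.
#' @export
apply_weight <- function(m, weight, p_c, p_u,
                         col_means = NULL, col_sds = NULL) {
  m <- as.matrix(m)
  if (p_c + p_u != ncol(m)) {
    stop(sprintf("matrix has %d columns but p_c + p_u = %d",
                 ncol(m), p_c + p_u))
  }
  if (length(weight) != 1L || weight <= 0) stop("weight must be a positive scalar")
  util_idx <- p_c + seq_len(p_u)
  m[, util_idx] <- m[, util_idx, drop = FALSE] * weight
  structure(list(matrix = m, col_means = col_means, col_sds = col_sds,
                 weight = weight, p_c = as.integer(p_c), p_u = as.integer(p_u)),
            class = "weighted_design")
}

#' Build the weighted clustering design from a cohort
#'
#' Standardizes the 33 condition and 7 utilization columns and multiplies
#' the utilization block by `weight_factor * sqrt(33/7)`. All distances,
#' WCSS values and validity indices downstream are computed in this weighted
#' space. `weight_factor` is the sensitivity-analysis dial (1 is the
#' balanced design; 0.5 and 2 are the perturbation limits).
#'
#' @param cohort A `cohort_matrix`.
#' @param weight_factor Scalar multiplier on the domain weight.
#' @return A `weighted_design`.
#' @export
build_design <- function(cohort, weight_factor = 1) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  x <- cbind(cohort$conditions, cohort$utilization)
  p_c <- ncol(cohort$conditions)
  p_u <- ncol(cohort$utilization)
  s <- standardize(x)
  w <- weight_factor * compute_domain_weight(p_c, p_u)
  apply_weight(s$matrix, w, p_c, p_u, col_means = s$col_means,
               col_sds = s$col_sds)
}

#' Build a weighted design from raw condition/utilization matrices
#'
#' Generic-schema counterpart of [build_design()] for constructed fixtures
#' and non-standard block sizes.
#'
#' @param conditions Numeric matrix (binary columns).
#' @param utilization Numeric matrix (count columns).
#' @param weight_factor Scalar multiplier on sqrt(p_c/p_u).
#' @return A `weighted_design`.
#' @export
build_design_matrices <- function(conditions, utilization, weight_factor = 1) {
  conditions <- as.matrix(conditions)
  utilization <- as.matrix(utilization)
  stopifnot(nrow(conditions) == nrow(utilization))
  p_c <- ncol(conditions)
  p_u <- ncol(utilization)
  s <- standardize(cbind(conditions, utilization))
  w <- weight_factor * compute_domain_weight(p_c, p_u)
  apply_weight(s$matrix, w, p_c, p_u, col_means = s$col_means,
               col_sds = s$col_sds)
}

#' Invert the standardization of a weighted design
#'
#' Recovers the raw input matrix from a design built by [build_design()]:
#' the utilization block is divided by the stored weight, then every column
#' is mapped back through its mean and standard deviation.
#'
#' @param design A `weighted_design` carrying `col_means` and `col_sds`.
#' @return The raw (unstandardized, unweighted) matrix.
#' @export
unstandardize <- function(design) {
  stopifnot(inherits(design, "weighted_design"),
            !is.null(design$col_means), !is.null(design$col_sds))
  m <- design$matrix
  util_idx <- design$p_c + seq_len(design$p_u)
  m[, util_idx] <- m[, util_idx, drop = FALSE] / design$weight
  sweep(sweep(m, 2L, design$col_sds, "*"), 2L, design$col_means, "+")
}

#' Export scaling parameters as a sidecar file
#'
#' Writes means, standard deviations and the applied weight as JSON so
#' external data can be projected into the same weighted space.
#'
#' @param design A `weighted_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaling <- function(design, path) {
  jsonlite::write_json(
    list(col_means = as.list(design$col_means),
         col_sds = as.list(design$col_sds),
         weight = design$weight, p_c = design$p_c, p_u = design$p_u),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.weighted_design <- function(x, ...) {
  cat(sprintf("<weighted_design> %d x (%d + %d) columns, utilization weight %.4f\n",
              nrow(x$matrix), x$p_c, x$p_u, x$weight))
  invisible(x)
}
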