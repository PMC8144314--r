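#' Pairwise SNP correlation (LD) from a reference panel
#'
#' Pearson correlation of dosage vectors for the requested SNPs, in the
#' requested order. Monomorphic reference SNPs (zero dosage variance) have
#' an undefined correlation and are assigned r = 0 off-diagonal -- the
#' independence value, which is conservative for an LD correction -- and
#' flagged.
#'
#' @param panel A `genotype_panel` (>= 2 samples).
#' @param snp_ids SNP ids to include; all must be present in the panel.
#' @return An `ld_matrix`: list with `snp_ids`, `r` (signed correlation,
#'   unit diagonal), and `monomorphic` (logical per SNP). Views `abs_r` and
#'   `r2` are available via [ld_view()].
#' @export
pairwise_r <- function(panel, snp_ids = NULL) {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  if (nrow(G) < 2) stop_param("need >= 2 reference samples for LD")
  if (is.null(snp_ids)) snp_ids <- colnames(G)
  missing_ids <- setdiff(snp_ids, colnames(G))
  if (length(missing_ids)) {
    abort(paste0("SNP(s) absent from reference panel: ",
                 paste(missing_ids, collapse = ", ")),
          class = "genewise_lookup_error")
  }
  X <- G[, snp_ids, drop = FALSE]
  v <- apply(X, 2, stats::var)
  mono <- v == 0
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(
    list(snp_ids = snp_ids, r = r, monomorphic = mono),
    class = "ld_matrix"
  )
}

#' Non-negative view of an LD matrix
#'
#' @param ld An `ld_matrix` (or bare correlation matrix).
#' @param mode `"abs_r"` (|r|, magnitude of the pairwise SNP correlation)
#'   or `"r2"` (squared correlation).
#' @return A numeric matrix with unit diagonal.
#' @export
ld_view <- function(ld, mode = c("abs_r", "r2")) {
  mode <- match.arg(mode)
  r <- if (inherits(ld, "ld_matrix")) ld$r else ld
  if (mode == "abs_r") abs(r) else r^2
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Adds an escalating ridge to the diagonal and renormalises back to unit
#' diagonal -- `(R + lambda * I) / (1 + lambda)` -- until a Cholesky
#' factorization succeeds. The ridge starts at `ridge_start`, escalates by
#' factors of 10 and is capped at 1e-2; the applied ridge is reported so
#' downstream callers can log it.
#'
#' @param r A symmetric correlation matrix (or `ld_matrix`).
#' @param ridge_start Initial ridge, default 1e-8.
#' @return List with `r` (repaired matrix), `chol` (upper-triangular
#'   factor) and `ridge` (0 if the input was already factorizable).
#' @export
make_psd <- function(r, ridge_start = 1e-8) {
  R <- if (inherits(r, "ld_matrix")) r$r else r
  if (!isSymmetric(unname(R), tol = 1e-8)) stop_param("correlation matrix must be symmetric")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) {
    return(list(r = R, chol = ch, ridge = 0))
  }
  lambda <- ridge_start
  while (lambda <= 1e-2) {
    Radj <- (R + diag(lambda, nrow(R))) / (1 + lambda)
    diag(Radj) <- 1
    ch <- tryCatch(chol(Radj), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(r = Radj, chol = ch, ridge = lambda))
    }
    lambda <- lambda * 10
  }
  abort("correlation matrix could not be repaired with ridge <= 1e-2",
        class = "genewise_conditioning_error")
}
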