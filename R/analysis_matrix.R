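# Encoded analysis design: outcome vector Y, treatment vector A, covariate
# matrix L with reference-coded categoricals, plus the encoding metadata that
# ties design columns back to original fields.

#' Build the encoded analysis matrix
#'
#' Encodes a filtered patient table into the design used by all estimation
#' stages: `Y` (binary outcome), `A` (treatment 0..3) and `L` (intercept plus
#' reference-coded indicators for each categorical covariate, binary flags
#' as 0/1, and any continuous covariate together with its square,
#' `<name>_sq`). Character covariates become factors with levels ordered by
#' decreasing frequency (ties alphabetical), so the reference level is the
#' most prevalent one; existing factor level orders are respected. Numeric
#' covariates taking only values 0/1 are treated as flags (no square term).
#'
#' @param records data.frame with `y5_survival`, `treatment` and the
#'   covariate columns.
#' @param covariates character vector of covariate column names; by default
#'   every column except the identifier/outcome/bookkeeping columns.
#' @return object of class `analysis_matrix`: list with `Y`, `A`, `L`,
#'   and `encoding` (per-covariate type, levels and design columns).
#' @export
analysis_matrix <- function(records, covariates = NULL) {
  for (cl in c("y5_survival", "treatment"))
    if (is.null(records[[cl]]))
      stop_drc("drc_schema", "missing required column(s): %s", cl)
  if (is.null(covariates)) {
    covariates <- setdiff(names(records),
                          c("patient_id", "first_dx_date", "med_history",
                            "treatment", "y5_survival", "followup_years"))
  }
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop_drc("drc_schema", "missing required column(s): %s",
             paste(miss, collapse = ", "))
  n <- nrow(records)
  Y <- as.numeric(records$y5_survival)
  A <- as.integer(records$treatment)
  if (anyNA(Y) || anyNA(A) || !all(A %in% 0:3))
    stop_drc("drc_schema", "Y/A contain missing or out-of-range values")

  L <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  encoding <- list()
  for (nm in covariates) {
    v <- records[[nm]]
    if (is.character(v)) {
      tab <- sort(table(v), decreasing = TRUE)
      ord <- names(tab)[order(-as.integer(tab), names(tab))]
      v <- factor(v, levels = ord)
    }
    if (is.factor(v)) {
      if (anyNA(v))
        stop_drc("drc_schema", "covariate '%s' has missing values", nm)
      lv <- levels(v)
      cols <- paste0(nm, lv[-1])
      M <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
      for (k in seq_along(cols)) M[, k] <- as.numeric(v == lv[k + 1])
      L <- cbind(L, M)
      encoding[[nm]] <- list(type = "factor", levels = lv, columns = cols)
    } else if (is.numeric(v)) {
      if (anyNA(v))
        stop_drc("drc_schema", "covariate '%s' has missing values", nm)
      if (all(v %in% c(0, 1))) {
        L <- cbind(L, stats::setNames(data.frame(v), nm)[[1]])
        colnames(L)[ncol(L)] <- nm
        encoding[[nm]] <- list(type = "flag", columns = nm)
      } else {
        sq <- paste0(nm, "_sq")
        L <- cbind(L, v, v^2)
        colnames(L)[ncol(L) - 1:0] <- c(nm, sq)
        encoding[[nm]] <- list(type = "continuous", columns = c(nm, sq))
      }
    } else {
      stop_drc("drc_schema", "covariate '%s' has unsupported type", nm)
    }
  }
  structure(list(Y = Y, A = A, L = L, encoding = encoding),
            class = "analysis_matrix")
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat("<analysis_matrix> n =", length(x$Y),
      " columns =", ncol(x$L), "\n")
  cat("  treatment counts:",
      paste(sprintf("%d:%d", 0:3, tabulate(x$A + 1L, 4)), collapse = " "),
      "\n")
  invisible(x)
}

# Row-subset an analysis_matrix (bootstrap resampling).
am_subset <- function(mat, idx) {
  structure(list(Y = mat$Y[idx], A = mat$A[idx],
                 L = mat$L[idx, , drop = FALSE], encoding = mat$encoding),
            class = "analysis_matrix")
}
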