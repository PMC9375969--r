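#' Encode expression relative to the gene's cohort median
#'
#' Converts an expression value into a five-level status by comparing it to
#' the gene's median across patients: below 0.05x the median is -2, from
#' 0.05x up to (but excluding) 0.75x is -1, above 1.25x and up to 1.75x is
#' 1, above 1.75x is 2, and the band around the median is 0. A gene whose
#' median is zero yields status 0 for zero values and 2 for any positive
#' value.
#'
#' @param value non-negative expression value(s).
#' @param gene_median non-negative median expression of the gene across
#'   patients (recycled against `value`).
#' @return integer status in -2..2, vectorized over `value`.
#' @export
expression_status <- function(value, gene_median) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("expression_status: negative expression value", call. = FALSE)
  }
  if (any(gene_median < 0, na.rm = TRUE)) {
    stop("expression_status: negative gene median", call. = FALSE)
  }
  m <- rep_len(gene_median, length(value))
  out <- integer(length(value))
  zero_m <- !is.na(m) & m == 0
  out[zero_m & value > 0] <- 2L
  reg <- !zero_m
  v <- value[reg]; mm <- m[reg]
  s <- integer(length(v))
  s[v < 0.05 * mm] <- -2L
  s[v >= 0.05 * mm & v < 0.75 * mm] <- -1L
  s[v > 1.25 * mm & v <= 1.75 * mm] <- 1L
  s[v > 1.75 * mm] <- 2L
  out[reg] <- s
  out[is.na(value) | is.na(m)] <- NA_integer_
  out
}

#' Expression status matrix for a cohort
#'
#' Applies [expression_status()] gene-wise, with each gene's median taken
#' across all supplied patients (pan-cancer, after QC filtering).
#'
#' @param expression numeric genes x patients matrix (rownames are Entrez
#'   IDs, colnames patient barcodes), non-negative.
#' @return integer matrix of the same shape with entries in -2..2.
#' @export
expression_status_matrix <- function(expression) {
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("expression_status_matrix: matrix must carry gene rownames and patient colnames",
         call. = FALSE)
  }
  med <- apply(expression, 1L, stats::median, na.rm = TRUE)
  out <- matrix(NA_integer_, nrow(expression), ncol(expression),
                dimnames = dimnames(expression))
  for (g in seq_len(nrow(expression))) {
    out[g, ] <- expression_status(expression[g, ], med[g])
  }
  out
}

#' Validate CNA calls against expression (GECNAV)
#'
#' A nonzero copy-number status is kept only if the gene's expression
#' status in the same patient has the same sign, in which case the CNA
#' status is replaced by the expression status; a sign mismatch (or a
#' neutral expression status) zeroes the call. Genes without expression
#' data pass through unchanged.
#'
#' @param cna integer genes x patients matrix with entries in -2..2
#'   (rownames Entrez IDs, colnames barcodes).
#' @param expr_status integer matrix from [expression_status_matrix()];
#'   genes or patients absent from it leave the CNA untouched.
#' @return validated CNA matrix, same shape and dimnames as `cna`.
#' @export
validate_cna <- function(cna, expr_status) {
  .check_status_levels(cna, -2:2, "validate_cna: CNA")
  .check_status_levels(expr_status, -2:2, "validate_cna: expression status")
  out <- cna
  common_g <- intersect(rownames(cna), rownames(expr_status))
  common_p <- intersect(colnames(cna), colnames(expr_status))
  if (length(common_g) == 0L || length(common_p) == 0L) return(out)
  cc <- cna[common_g, common_p, drop = FALSE]
  ee <- expr_status[common_g, common_p, drop = FALSE]
  val <- cc
  nonzero <- !is.na(cc) & cc != 0
  known <- nonzero & !is.na(ee)
  concordant <- known & sign(cc) == sign(ee) & ee != 0
  val[known] <- 0L
  val[concordant] <- ee[concordant]
  out[common_g, common_p] <- val
  out
}

.check_status_levels <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(what, " status outside {", paste(range(levels), collapse = ".."),
         "}", call. = FALSE)
  }
  invisible(TRUE)
}
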