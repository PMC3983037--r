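#' Genotype matrix container
#'
#' A minimal container for biallelic genotypes of `n` individuals at `m`
#' SNPs, coded as reference-allele counts 0/1/2 (`NA` for missing), with
#' per-SNP allele frequencies.  Frequencies default to in-sample estimates
#' (allele count over non-missing chromosomes), matching common GRM
#' practice; external frequencies may be supplied, e.g. to study the bias
#' of the relatedness estimator.
#'
#' @param counts `n x m` numeric/integer matrix of allele counts in
#'   \{0, 1, 2, NA\}.
#' @param ids Individual identifiers; default taken from `rownames(counts)`
#'   or generated.
#' @param freqs Optional per-SNP allele frequencies in (0, 1).
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(rbind(c(2, 1, 0), c(0, 1, 2)))
#' @export
genotype_matrix <- function(counts, ids = NULL, freqs = NULL) {
  counts <- as.matrix(counts)
  ok <- is.na(counts) | counts == 0 | counts == 1 | counts == 2
  if (!all(ok)) stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(ids)) {
    ids <- rownames(counts)
    if (is.null(ids)) ids <- sprintf("id%d", seq_len(nrow(counts)))
  }
  if (length(ids) != nrow(counts)) {
    stop("`ids` length must match the number of rows of `counts`",
         call. = FALSE)
  }
  if (!is.null(freqs)) {
    if (length(freqs) != ncol(counts) || any(freqs <= 0) || any(freqs >= 1)) {
      stop("`freqs` must give one frequency in (0, 1) per SNP", call. = FALSE)
    }
  } else {
    freqs <- colMeans(counts, na.rm = TRUE) / 2
  }
  structure(list(counts = counts, ids = as.character(ids), freqs = freqs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' SNP-derived genetic relationship matrix
#'
#' Computes the GRM of Yang et al. (2010):
#' \deqn{A_{jk} = \frac{1}{M}\sum_i
#'   \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)},}
#' with the diagonal given by the same expression at `j = k`.  Relatedness
#' is referenced to the current sample, so off-diagonals are distributed
#' about zero and may be negative.  Monomorphic SNPs are dropped (with a
#' message).  Missing genotypes are handled per pair, complete-case: a
#' SNP contributes to \eqn{A_{jk}} only if both individuals are called
#' there, and the per-pair divisor `n_snps` counts the SNPs actually used.
#'
#' @param g A [genotype_matrix()].
#' @return An object of class `grm`: list with `ids`, `A` (symmetric
#'   `n x n` matrix), `n_snps` (matrix of per-pair SNP counts), `m`
#'   (polymorphic SNPs used) and `n_dropped` (monomorphic SNPs removed).
#' @examples
#' g <- genotype_matrix(rbind(c(2, 0), c(0, 2)), freqs = c(0.5, 0.5))
#' compute_grm(g)$A
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$counts
  p <- g$freqs
  if (nrow(x) < 2) stop("need at least 2 individuals", call. = FALSE)
  poly <- p > 0 & p < 1 & !is.na(p)
  n_dropped <- sum(!poly)
  if (n_dropped > 0) {
    message(sprintf("dropping %d monomorphic SNP(s)", n_dropped))
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- ncol(x)
  if (m < 1) stop("no polymorphic SNPs left", call. = FALSE)
  w <- sweep(x, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  if (anyNA(w)) {
    obs <- !is.na(w)
    w[!obs] <- 0
    n_snps <- tcrossprod(obs * 1)
    if (any(n_snps == 0)) {
      stop("at least one pair of individuals shares no called SNP",
           call. = FALSE)
    }
    A <- tcrossprod(w) / n_snps
  } else {
    A <- tcrossprod(w) / m
    n_snps <- matrix(m, nrow(x), nrow(x))
  }
  dimnames(A) <- list(g$ids, g$ids)
  structure(list(ids = g$ids, A = A, n_snps = n_snps, m = m,
                 n_dropped = n_dropped),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat(sprintf("GRM: %d individuals, %d SNPs\n", length(x$ids), x$m))
  cat(sprintf("  off-diagonal mean %.2e, variance %.3e; diagonal mean %.4f\n",
              mean(off), stats::var(off), mean(diag(x$A))))
  invisible(x)
}

#' Empirical variance of SNP-derived relatedness
#'
#' Variance of the off-diagonal GRM entries — the quantity that scales
#' every sampling-variance approximation in the package.  By default,
#' pairs with relatedness above 0.025 are excluded first, the conventional
#' stringent threshold for removing cryptic relatedness from nominally
#' unrelated samples; cryptic relatives inflate the variance and change
#' the estimand.
#'
#' @param grm A [compute_grm()] / [read_grm()] object.
#' @param relatedness_cutoff Exclude pairs with `A_jk` above this value
#'   before taking the variance; `NULL` keeps all pairs.
#' @return The variance of the retained off-diagonal entries.  For
#'   independent SNPs in Hardy-Weinberg and linkage equilibrium this is
#'   approximately `1/m`; for genome-wide common SNPs in humans it is
#'   approximately `2e-5`.
#' @examples
#' g <- simulate_genotypes(n = 200, m = 500, seed = 1)
#' empirical_var_pi(compute_grm(g))  # ~ 1/500
#' @export
empirical_var_pi <- function(grm, relatedness_cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"))
  if (length(grm$ids) < 3) stop("need at least 3 individuals", call. = FALSE)
  off <- grm$A[upper.tri(grm$A)]
  if (!is.null(relatedness_cutoff)) off <- off[off <= relatedness_cutoff]
  if (length(off) < 2) {
    stop("fewer than 2 pairs retained after the relatedness cutoff",
         call. = FALSE)
  }
  stats::var(off)
}

#' Read and write GRMs in GCTA plain-text format
#'
#' The text dialect of the GCTA GRM format: `<prefix>.grm` holds
#' whitespace-separated triplets `index1 index2 n_snps value` (1-based,
#' lower triangle including the diagonal, `index1 >= index2`) and
#' `<prefix>.grm.id` holds one `FID IID` pair per line.  Values round-trip
#' to 6 decimal places.  With `gz = TRUE` the triplet file is
#' gzip-compressed as `<prefix>.grm.gz` (the reader accepts either).
#'
#' @param grm A `grm` object.
#' @param prefix Path prefix for the `.grm`/`.grm.gz` and `.grm.id` files.
#' @param gz Write the triplet file gzip-compressed.
#' @return `write_grm` returns the prefix invisibly; `read_grm` returns a
#'   `grm` object with the full symmetric matrix reconstructed.
#' @examples
#' g <- compute_grm(simulate_genotypes(20, 50, seed = 1))
#' pre <- file.path(tempdir(), "toy")
#' write_grm(g, pre)
#' all.equal(read_grm(pre)$A, g$A, tolerance = 1e-6)
#' @export
write_grm <- function(grm, prefix, gz = FALSE) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  tri <- data.frame(i = idx[, 1], j = idx[, 2],
                    n_snps = grm$n_snps[idx],
                    value = sprintf("%.6f", grm$A[idx]))
  path <- paste0(prefix, if (gz) ".grm.gz" else ".grm")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  utils::write.table(tri, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  close(con)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(prefix, ".grm.id"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  id_path <- paste0(prefix, ".grm.id")
  if (!file.exists(id_path)) stop("missing id file: ", id_path, call. = FALSE)
  id <- utils::read.table(id_path, header = FALSE,
                          colClasses = "character")
  ids <- id[[2]]
  n <- length(ids)
  tri_path <- paste0(prefix, ".grm")
  if (!file.exists(tri_path)) tri_path <- paste0(prefix, ".grm.gz")
  if (!file.exists(tri_path)) {
    stop("missing GRM triplet file for prefix: ", prefix, call. = FALSE)
  }
  lines <- readLines(tri_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) != 4L)
  if (length(bad) > 0) {
    stop(sprintf("malformed GRM line %d: expected 4 fields", bad[1]),
         call. = FALSE)
  }
  tri <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  if (anyNA(tri)) {
    stop("malformed GRM line: non-numeric field", call. = FALSE)
  }
  if (max(tri[, 1:2]) > n) {
    stop(sprintf("GRM indices run to %d but the id file lists %d individuals",
                 max(tri[, 1:2]), n), call. = FALSE)
  }
  if (any(tri[, 1] < tri[, 2])) {
    stop("GRM triplets must be lower-triangular (index1 >= index2)",
         call. = FALSE)
  }
  A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  n_snps <- matrix(NA_real_, n, n)
  A[tri[, 1:2, drop = FALSE]] <- tri[, 4]
  n_snps[tri[, 1:2, drop = FALSE]] <- tri[, 3]
  if (anyNA(A[lower.tri(A, diag = TRUE)])) {
    stop("GRM triplet file does not cover the full lower triangle",
         call. = FALSE)
  }
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  n_snps[upper.tri(n_snps)] <- t(n_snps)[upper.tri(n_snps)]
  structure(list(ids = ids, A = A, n_snps = n_snps,
                 m = max(n_snps), n_dropped = NA_integer_),
            class = "grm")
}

#' Read and write phenotype files
#'
#' Whitespace-delimited `FID IID value` phenotype files (GCTA `.phen`
#' style); missing phenotypes are `NA`.
#'
#' @param path File path.
#' @param ids Individual identifiers (used for both FID and IID).
#' @param y Phenotype values.
#' @return `read_phen` returns a data frame with columns `id` and `y`;
#'   `write_phen` returns `path` invisibly.
#' @export
read_phen <- function(path) {
  d <- utils::read.table(path, header = FALSE, na.strings = c("NA", "-9"),
                         colClasses = c("character", "character", "numeric"))
  data.frame(id = d[[2]], y = d[[3]])
}

#' @rdname read_phen
#' @export
write_phen <- function(path, ids, y) {
  stopifnot(length(ids) == length(y))
  utils::write.table(data.frame(ids, ids, y), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
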