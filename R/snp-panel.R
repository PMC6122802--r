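#' Construct a SNP panel for polygenic risk scoring
#'
#' A SNP panel holds, for each variant, its identifier, risk allele, risk
#' allele frequency and per-allele odds ratio. The polygenic risk score weight
#' of each SNP is the natural logarithm of its odds ratio.
#'
#' @param rsid character vector of SNP identifiers.
#' @param risk_allele character vector of risk alleles (A/C/G/T).
#' @param risk_allele_freq numeric vector of risk-allele frequencies in (0, 1).
#' @param odds_ratio numeric vector of per-allele odds ratios (> 0).
#' @return An object of class `snp_panel`: a data frame with columns `rsid`,
#'   `risk_allele`, `risk_allele_freq`, `odds_ratio` and `weight`
#'   (`log(odds_ratio)`).
#' @seealso [compute_prs()], [read_snp_panel()]
#' @export
#' @examples
#' snp_panel(c("rs1", "rs2"), c("A", "G"), c(0.3, 0.45), c(1.10, 1.22))
snp_panel <- function(rsid, risk_allele, risk_allele_freq, odds_ratio) {
  n <- length(rsid)
  if (length(risk_allele) != n || length(risk_allele_freq) != n ||
      length(odds_ratio) != n) {
    stop("all snp_panel columns must have the same length", call. = FALSE)
  }
  if (anyDuplicated(rsid)) stop("duplicated rsid in SNP panel", call. = FALSE)
  if (any(odds_ratio <= 0)) stop("odds ratios must be > 0", call. = FALSE)
  if (any(risk_allele_freq <= 0 | risk_allele_freq >= 1)) {
    stop("risk allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  out <- data.frame(
    rsid = as.character(rsid),
    risk_allele = as.character(risk_allele),
    risk_allele_freq = as.numeric(risk_allele_freq),
    odds_ratio = as.numeric(odds_ratio),
    weight = log(as.numeric(odds_ratio)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Read a SNP panel from CSV
#'
#' Expects columns `rsid`, `risk_allele`, `risk_allele_freq`, `odds_ratio`.
#' The log-odds-ratio weight column is recomputed on read.
#'
#' @param path path to the CSV file.
#' @return A [snp_panel()] object.
#' @export
#' @examples
#' panel <- read_snp_panel(bcriskaug_extdata("snp_panel_synthetic.csv"))
#' nrow(panel)
read_snp_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rsid", "risk_allele", "risk_allele_freq", "odds_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("SNP panel CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  snp_panel(df$rsid, df$risk_allele, df$risk_allele_freq, df$odds_ratio)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "variants; per-allele OR range [",
      format(min(x$odds_ratio), digits = 3), ",",
      format(max(x$odds_ratio), digits = 3), "]\n")
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

#' Compute a polygenic risk score from risk-allele counts
#'
#' The raw score of a subject is the sum over SNPs of the risk-allele count
#' (0, 1 or 2) multiplied by the log odds ratio of the SNP, i.e. a
#' multiplicative joint-effects model on the odds scale. A missing genotype is
#' replaced by its expected dosage `2 * risk_allele_freq` under
#' Hardy-Weinberg equilibrium.
#'
#' @param genotypes numeric vector (one subject) or matrix (subjects in rows)
#'   of risk-allele counts in `{0, 1, 2}`; `NA` allowed.
#' @param panel a [snp_panel()]; columns of `genotypes` must align with its
#'   rows.
#' @return Numeric vector of raw (unstandardised) scores.
#' @seealso [standardize_prs()]
#' @export
#' @examples
#' panel <- snp_panel(c("rs1", "rs2"), c("A", "G"), c(0.3, 0.45), c(1.1, 1.2))
#' compute_prs(c(1, 2), panel)     # 1*log(1.1) + 2*log(1.2)
#' compute_prs(c(NA, 0), panel)    # 2*0.3*log(1.1)
compute_prs <- function(genotypes, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(panel)) {
    stop("genotype vector length (", ncol(genotypes),
         ") does not match panel size (", nrow(panel), ")", call. = FALSE)
  }
  ok <- is.na(genotypes) | (genotypes %in% c(0, 1, 2))
  if (!all(ok)) stop("genotypes must be risk-allele counts in {0, 1, 2} or NA",
                     call. = FALSE)
  if (anyNA(genotypes)) {
    expected <- matrix(2 * panel$risk_allele_freq, nrow(genotypes),
                       ncol(genotypes), byrow = TRUE)
    genotypes[is.na(genotypes)] <- expected[is.na(genotypes)]
  }
  drop(genotypes %*% panel$weight)
}

#' Standardise polygenic risk scores across all participants
#'
#' Converts raw scores to mean 0 and standard deviation 1 over the pooled set
#' of cases and controls, using the population (n-denominator) standard
#' deviation.
#'
#' @param raw numeric vector of raw scores over all participants.
#' @return Numeric vector of standardised scores.
#' @export
#' @examples
#' standardize_prs(c(1, 2, 3))
standardize_prs <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 2) stop("need at least 2 subjects to standardise",
                            call. = FALSE)
  s <- pop_sd(raw)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardise",
                                    call. = FALSE)
  (raw - mean(raw)) / s
}
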