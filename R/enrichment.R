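# Case-control enrichment of cardiac phenotype among candidate-gene LOF
# carriers: a 2x2 contingency table, odds ratio, and Wald confidence
# interval on the log odds ratio.

#' Build the carrier-by-phenotype 2x2 table
#'
#' Cells: `a` carriers with phenotype, `b` carriers without, `c`/`d` the
#' comparison group with/without phenotype. The default comparison group
#' is the whole cohort (carriers included in the background); the
#' alternative restricts it to non-carriers.
#'
#' @param carrier Logical vector per sample.
#' @param phenotype Logical vector per sample, aligned with `carrier`.
#' @param comparison `"whole_cohort"` (default) or `"noncarriers"`.
#' @return List of class `ContingencyTable` with integer `a`, `b`, `c`, `d`.
#' @export
build_table <- function(carrier, phenotype,
                        comparison = c("whole_cohort", "noncarriers")) {
  comparison <- match.arg(comparison)
  stopifnot(length(carrier) == length(phenotype))
  if (!length(carrier)) stop("empty cohort")
  a <- sum(carrier & phenotype)
  b <- sum(carrier & !phenotype)
  comp <- if (comparison == "whole_cohort") rep(TRUE, length(carrier))
          else !carrier
  if (!any(comp)) stop("empty comparison group")
  cc <- sum(comp & phenotype)
  d <- sum(comp & !phenotype)
  structure(list(a = a, b = b, c = cc, d = d, comparison = comparison),
            class = "ContingencyTable")
}

as_table <- function(t) {
  if (inherits(t, "ContingencyTable") || is.list(t)) t
  else stop("expected a ContingencyTable or list(a, b, c, d)")
}

#' Odds ratio of a 2x2 table
#'
#' OR = (a d)/(b c). When any cell is zero and `zero_correction` is on,
#' 0.5 is added to every cell first (Haldane-Anscombe).
#'
#' @param t `ContingencyTable` or list with a, b, c, d.
#' @param zero_correction Default `TRUE`.
#' @return Odds ratio.
#' @export
odds_ratio <- function(t, zero_correction = TRUE) {
  t <- as_table(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!zero_correction) {
      if (t$b * t$c == 0) stop("odds ratio undefined: zero denominator cell")
    } else cells <- cells + 0.5
  }
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Wald confidence interval for the odds ratio
#'
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)), on the Haldane-Anscombe
#' corrected cells when a zero cell is present and correction is on.
#'
#' @param t `ContingencyTable` or list with a, b, c, d.
#' @param z Normal quantile (default 1.96 for 95%).
#' @param zero_correction Default `TRUE`.
#' @return Numeric `c(lower, upper)`.
#' @export
wald_ci <- function(t, z = 1.96, zero_correction = TRUE) {
  t <- as_table(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!zero_correction) stop("Wald CI undefined with a zero cell")
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  exp(log(or) + c(-1, 1) * z * se)
}

#' Read carrier/phenotype flags from TSV
#'
#' Columns: sample, carrier, phenotype (0/1 or TRUE/FALSE).
#'
#' @param path TSV path.
#' @return data.frame with logical carrier and phenotype columns.
#' @export
read_carrier_flags <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  p$carrier <- as.logical(p$carrier)
  p$phenotype <- as.logical(p$phenotype)
  p
}

#' Enrichment report for a carrier/phenotype cohort
#'
#' @param flags data.frame from [read_carrier_flags()].
#' @param comparison See [build_table()].
#' @param z Normal quantile for the CI.
#' @return One-row data.frame: a, b, c, d, odds_ratio, ci_lower, ci_upper,
#'   method.
#' @export
enrichment_report <- function(flags, comparison = "whole_cohort", z = 1.96) {
  t <- build_table(flags$carrier, flags$phenotype, comparison)
  ci <- wald_ci(t, z = z)
  data.frame(a = t$a, b = t$b, c = t$c, d = t$d,
             odds_ratio = odds_ratio(t),
             ci_lower = ci[1], ci_upper = ci[2],
             method = "wald_log_or")
}
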