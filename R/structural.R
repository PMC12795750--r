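#' Historical redlining score (HRS)
#'
#' Area-weighted summary of 1930s HOLC grades over a tract. With
#' overlap proportions `A..D` (area fractions of the tract covered by
#' each grade) and `total = A+B+C+D`, the score is
#' `(1*A + 2*B + 3*C + 4*D) / total`, defined only when the tract has at
#' least 20% overlap with HOLC-graded neighborhoods (`total >= 0.20`,
#' inclusive). Higher scores indicate worse grades; grade D is the
#' historically redlined class. Vectorized.
#'
#' @param a,b,c_,d Overlap proportions for grades A-D, each in `[0,1]`
#'   with `a+b+c_+d <= 1`.
#' @return HRS in `[1, 4]`, or `NA` below the 20% overlap floor.
#' @export
compute_hrs <- function(a, b, c_, d) {
  for (v in list(a, b, c_, d)) {
    if (any(v < 0 | v > 1)) stop("overlap proportions must lie in [0, 1]")
  }
  total <- a + b + c_ + d
  if (any(total > 1 + 1e-9)) stop("overlap proportions must sum to <= 1")
  ifelse(total >= 0.20, (1 * a + 2 * b + 3 * c_ + 4 * d) / total, NA_real_)
}

#' Mortgage-discrimination index D
#'
#' Ratio of the minority share of mortgage loans (1990-2000) to the
#' minority share of households (2000):
#' `D = (L_minority/L_total) / (H_minority/H_total)`. A value below 1
#' indicates lending discrimination against racial and ethnic minority
#' residents. Vectorized.
#'
#' @param l_minority,l_total Loan counts to minority and to all
#'   borrowers.
#' @param h_minority,h_total Household counts, minority and all.
#' @return D (>= 0), or `NA` when `l_total`, `h_total` or `h_minority`
#'   is zero.
#' @export
compute_mortgage_discrimination <- function(l_minority, l_total,
                                            h_minority, h_total) {
  if (any(c(l_minority, l_total, h_minority, h_total) < 0))
    stop("counts must be non-negative")
  undef <- l_total == 0 | h_total == 0 | h_minority == 0
  out <- (l_minority / l_total) / (h_minority / h_total)
  out[undef] <- NA_real_
  out
}

#' Sustained-discrimination classification
#'
#' `TRUE` iff the mortgage-discrimination index is strictly below 1
#' (missing in, missing out). Vectorized.
#'
#' @param d_index Mortgage-discrimination index.
#' @export
classify_sustained <- function(d_index) {
  ifelse(is.na(d_index), NA, d_index < 1)
}

#' Per-tract structural-racism indices
#'
#' Joins the HOLC-overlap and mortgage tables into one row per tract
#' carrying the historical redlining score, the mortgage-discrimination
#' index and the sustained-discrimination flag.
#'
#' @param holc HOLC overlap table (`tract_id`, `overlap_a` ..
#'   `overlap_d`, `total_graded`).
#' @param mortgage Mortgage table (`tract_id`, `loans_minority`,
#'   `loans_total`, `households_minority`, `households_total`).
#' @return A `StructuralIndices` data.frame: `tract_id`, `hrs`,
#'   `d_index`, `sustained`.
#' @export
structural_indices <- function(holc, mortgage) {
  h <- data.frame(tract_id = holc$tract_id,
                  hrs = compute_hrs(holc$overlap_a, holc$overlap_b,
                                    holc$overlap_c, holc$overlap_d),
                  stringsAsFactors = FALSE)
  m <- data.frame(tract_id = mortgage$tract_id,
                  d_index = compute_mortgage_discrimination(
                    mortgage$loans_minority, mortgage$loans_total,
                    mortgage$households_minority, mortgage$households_total),
                  stringsAsFactors = FALSE)
  out <- merge(h, m, by = "tract_id", all = TRUE)
  out$sustained <- classify_sustained(out$d_index)
  out
}
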