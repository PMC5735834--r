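#' Paired absolute and relative differences
#'
#' For paired measurements of the same quantity, computes the differences
#' `d_i = reference_i - other_i` and the relative differences normalized to
#' the average of each pair, `rel_i = 100 * d_i / ((reference_i + other_i)/2)`
#' (in percent), and returns the mean and SD (denominator n - 1) of both.
#'
#' @param reference,other Numeric vectors of equal length >= 2; all values
#'   must be positive for the relative form to be meaningful.
#' @return A list with `mean_diff`, `sd_diff`, `mean_rel_pct`, `sd_rel_pct`.
#' @export
#' @examples
#' paired_differences(c(110, 100), c(90, 100))
paired_differences <- function(reference, other) {
  if (length(reference) != length(other))
    stop("vectors must have equal length", call. = FALSE)
  if (length(reference) < 2L)
    stop("need at least 2 pairs (SD undefined at n = 1)", call. = FALSE)
  avg <- (reference + other) / 2
  if (any(avg == 0)) {
    bad <- which(avg == 0)[1]
    stop(sprintf("pair %d averages to zero; relative difference undefined", bad),
         call. = FALSE)
  }
  d <- reference - other
  rel <- 100 * d / avg
  list(mean_diff = mean(d), sd_diff = stats::sd(d),
       mean_rel_pct = mean(rel), sd_rel_pct = stats::sd(rel))
}

#' Pearson correlation coefficient
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return Sample Pearson correlation in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(a, b)
}

#' Two-tailed paired Student's t-test
#'
#' Tests the paired differences `d = a - b` against zero mean:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom. When all
#' differences are exactly zero the test is the null case (`t = 0, p = 1`);
#' identical nonzero differences (zero SD, nonzero mean) are degenerate and
#' raise an error.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return List with `t` and the two-tailed `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    stop("zero SD of nonzero differences; paired t-test degenerate", call. = FALSE)
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Comparison against a gold-standard measurement
#'
#' Percentage differences of image-derived left-ventricular mass from the
#' gold-standard (ex-vivo) value: `pct_i = 100 * (image_i - gold_i) / gold_i`.
#' Unlike [paired_differences()], the denominator is the gold value itself,
#' not the average of the pair. Returns the mean and SD of the percentage
#' differences and the Pearson correlation between the two vectors.
#'
#' @param lvm_image Image-derived masses, mg.
#' @param lvm_gold Gold-standard masses, mg; all > 0.
#' @return List with `mean_pct`, `sd_pct`, `r`.
#' @export
exvivo_comparison <- function(lvm_image, lvm_gold) {
  if (length(lvm_image) != length(lvm_gold) || length(lvm_gold) < 3L)
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  if (any(lvm_gold <= 0))
    stop("gold-standard values must be positive", call. = FALSE)
  pct <- 100 * (lvm_image - lvm_gold) / lvm_gold
  list(mean_pct = mean(pct), sd_pct = stats::sd(pct),
       r = pearson_r(lvm_image, lvm_gold))
}

#' Significance stars
#'
#' Conventional three-level marks: `*` for p <= 0.05, `**` for p <= 0.01,
#' `***` for p <= 0.001, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*", TRUE ~ "")
}

lv_parameters <- c("EDV", "ESV", "EF", "LVM")
param_cols <- c(EDV = "edv_ul", ESV = "esv_ul", EF = "ef_pct", LVM = "lvm_mg")

# one agreement row: mean/SD of absolute and relative differences,
# correlation, paired-test p and stars
agreement_row <- function(reference, other, parameter) {
  pd <- paired_differences(reference, other)
  r <- tryCatch(pearson_r(reference, other), error = function(e) NA_real_)
  tt <- paired_ttest(reference, other)
  tibble::tibble(
    parameter = parameter,
    mean_diff = pd$mean_diff, sd_diff = pd$sd_diff,
    mean_rel_pct = pd$mean_rel_pct, sd_rel_pct = pd$sd_rel_pct,
    r = r, p = tt$p, n = length(reference),
    stars = significance_stars(tt$p)
  )
}

#' Observer-agreement tables
#'
#' Assembles the intra-observer (observer 1, repeat 1 vs repeat 2),
#' inter-observer (observer 1 repeat 1 vs observer 2) and gold-standard
#' (LVM only) agreement tables from a table of per-measurement cardiac
#' function values. Observer 1's first measurement is always the reference.
#'
#' @param functions A tibble with columns `subject`, `condition`, `observer`,
#'   `rep`, `edv_ul`, `esv_ul`, `ef_pct`, `lvm_mg` (one row per measurement).
#' @param gold Optional tibble with columns `subject`, `lvm_mg` — the
#'   gold-standard (ex-vivo stand-in) masses.
#' @return List of tibbles `intra`, `inter` and (if `gold` given) `gold`; the
#'   first two have one row per condition x parameter with the columns of
#'   [agreement_row]: mean/SD of absolute and relative differences (the
#'   relative form normalized to the pair average), Pearson r, paired-test p,
#'   n, and significance stars.
#' @export
build_table <- function(functions, gold = NULL) {
  need <- c("subject", "condition", "observer", "rep", unname(param_cols))
  if (!all(need %in% names(functions)))
    stop("`functions` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  conditions <- unique(functions$condition)
  get_vals <- function(cond, obs, rp) {
    x <- dplyr::filter(functions, .data$condition == cond,
                       .data$observer == obs, .data$rep == rp)
    dplyr::arrange(x, .data$subject)
  }
  one_study <- function(obs2, rep2, study_name) {
    purrr::map_dfr(conditions, function(cond) {
      ref <- get_vals(cond, 1L, 1L)
      oth <- get_vals(cond, obs2, rep2)
      if (nrow(ref) == 0L || nrow(oth) == 0L || nrow(ref) != nrow(oth)) {
        warning(sprintf("missing %s measurements for condition %s; rows omitted",
                        study_name, cond), call. = FALSE)
        return(tibble::tibble())
      }
      purrr::map_dfr(lv_parameters, function(prm) {
        agreement_row(ref[[param_cols[prm]]], oth[[param_cols[prm]]], prm)
      }) |>
        dplyr::mutate(condition = cond, study = study_name, .before = 1)
    })
  }
  out <- list(intra = one_study(1L, 2L, "intra"),
              inter = one_study(2L, 1L, "inter"))
  if (!is.null(gold)) {
    gold <- dplyr::arrange(gold, .data$subject)
    out$gold <- purrr::map_dfr(conditions, function(cond) {
      purrr::map_dfr(unique(functions$observer), function(obs) {
        x <- get_vals(cond, obs, 1L)
        if (nrow(x) != nrow(gold)) return(tibble::tibble())
        ev <- exvivo_comparison(x$lvm_mg, gold$lvm_mg)
        tibble::tibble(condition = cond, observer = obs, parameter = "LVM",
                       mean_pct = ev$mean_pct, sd_pct = ev$sd_pct, r = ev$r,
                       n = nrow(gold))
      })
    })
  }
  out
}
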