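#' Recompute group statistics from deposited per-participant tables
#'
#' Reads the per-figure data deposit — either an XLSX workbook or a directory
#' of CSV files, one per sheet — and recomputes the group statistics of the
#' selected analysis from the per-participant values.
#'
#' Expected sheet schemas (column names matched exactly):
#' \describe{
#'   \item{behavior}{`subject`, `S90`, `S15` — group means, paired t of
#'     90 vs 15 sensitivity, mean behavioral saliency score.}
#'   \item{laminar}{`subject`, `roi`, `depth`, `SS` — per-ROI one-way
#'     rm-ANOVA of the saliency contrast across depths.}
#'   \item{connectivity}{`subject`, `delta_ff`, `delta_fb` — one-sample t per
#'     pathway (Holm corrected) and the paired t of feedforward vs feedback.}
#'   \item{bcea}{`subject`, `theta`, `bcea` — one-way rm-ANOVA of fixation
#'     BCEA across orientation-contrast conditions.}
#' }
#'
#' @param path Path to an `.xlsx` workbook or a directory containing
#'   `<sheet>.csv` files.
#' @param which One of `"behavior"`, `"laminar"`, `"connectivity"`, `"bcea"`.
#' @return A tibble of recomputed statistics (one row per quantity).
#' @export
reproduce_deposited <- function(path, which = c("behavior", "laminar",
                                                "connectivity", "bcea")) {
  which <- match.arg(which)
  tab <- read_deposited_sheet(path, which)

  if (which == "behavior") {
    need_cols(tab, c("subject", "S90", "S15"), "behavior")
    tt <- paired_t(tab$S90, tab$S15)
    ss <- behavioral_saliency(tab$S90, tab$S15)$SS_behavior
    tibble::tibble(
      quantity = c("mean_S90", "mean_S15", "mean_SS_behavior",
                   "t_90_vs_15", "df", "p"),
      value = c(mean(tab$S90), mean(tab$S15), mean(ss), tt$t, tt$df, tt$p))
  } else if (which == "connectivity") {
    need_cols(tab, c("subject", "delta_ff", "delta_fb"), "connectivity")
    tt <- paired_t(tab$delta_ff, tab$delta_fb)
    p1 <- stats::t.test(tab$delta_ff)$p.value
    p2 <- stats::t.test(tab$delta_fb)$p.value
    ph <- holm_correct(c(p1, p2))
    tibble::tibble(
      quantity = c("mean_delta_ff", "mean_delta_fb", "t_ff_vs_fb", "df", "p",
                   "p_ff_holm", "p_fb_holm"),
      value = c(mean(tab$delta_ff), mean(tab$delta_fb), tt$t, tt$df, tt$p,
                ph[1], ph[2]))
  } else if (which == "laminar") {
    need_cols(tab, c("subject", "roi", "depth", "SS"), "laminar")
    out <- lapply(unique(tab$roi), function(k) {
      av <- rm_anova(tab[tab$roi == k, ], "SS", "depth")
      tibble::tibble(
        quantity = paste0(k, c("_F", "_df1", "_df2", "_p")),
        value = c(av$F[1], av$df1[1], av$df2[1], av$p[1]))
    })
    do.call(rbind, out)
  } else {
    need_cols(tab, c("subject", "theta", "bcea"), "bcea")
    av <- rm_anova(tab, "bcea", "theta")
    tibble::tibble(quantity = c("F", "df1", "df2", "p"),
                   value = c(av$F[1], av$df1[1], av$df2[1], av$p[1]))
  }
}

read_deposited_sheet <- function(path, sheet) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$")
    found <- sub("\\.csv$", "", files)
    if (!sheet %in% found) {
      stop_invalid("sheet '%s' not found; available sheets: %s",
                   sheet, paste(found, collapse = ", "))
    }
    utils::read.csv(file.path(path, paste0(sheet, ".csv")))
  } else if (file.exists(path) && grepl("\\.xlsx?$", path)) {
    found <- tryCatch(readxl::excel_sheets(path),
                      error = function(e) stop_invalid("cannot read workbook %s: %s", path, conditionMessage(e)))
    if (!sheet %in% found) {
      stop_invalid("sheet '%s' not found; available sheets: %s",
                   sheet, paste(found, collapse = ", "))
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    stop_invalid("path %s is neither an xlsx workbook nor a sheet directory", path)
  }
}

need_cols <- function(tab, cols, sheet) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    stop_invalid("sheet '%s' is missing column(s) %s; found: %s", sheet,
                 paste(missing, collapse = ", "), paste(names(tab), collapse = ", "))
  }
  invisible(tab)
}
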