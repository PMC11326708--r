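# CSV and plot exports: per-tube densitometry, SB/LS spectra, CWT
# heatmap, and a combined periods table. All CSVs use '.' decimals,
# comma separators and a header row.

export_stem <- function(r) {
  sprintf("%s_tube%02d", gsub("[^A-Za-z0-9_-]", "_", r$pack_name),
          r$tube_index)
}

#' Export analysis data and plots for a set of tube records
#'
#' Per tube: a densitometry CSV (`tube_index, x_px, raw, smoothed,
#' interpolated`) with plot, Sokolove-Bushell and Lomb-Scargle spectrum
#' CSVs (`period_h, power`) with plots, and the CWT amplitude matrix CSV
#' (rows = time points, columns = periods) with a heatmap. One combined
#' periods table (`pack, tube, method, period_h, growth_rate_mm_per_h`)
#' covers all records.
#'
#' @param records list of `tube_record`.
#' @param outdir output directory (created if needed).
#' @param band_h circadian search band in hours.
#' @param window optional mark window passed to [all_periods()].
#' @return data.frame inventory of the files written, invisibly.
#' @export
export_all <- function(records, outdir, band_h = RT_BAND_H, window = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  periods_tab <- NULL
  for (r in records) {
    stem <- file.path(outdir, export_stem(r))
    pr <- record_profiles(r)
    marks <- record_marks(r)
    cal <- fit_time_calibration(marks)

    dens <- data.frame(tube_index = r$tube_index,
                       x_px = seq_along(pr$raw$values),
                       raw = pr$raw$values,
                       smoothed = pr$band_smoothed$values,
                       interpolated = pr$interpolated$values)
    f <- paste0(stem, "_densitometry.csv")
    write.csv(dens, f, row.names = FALSE)
    files <- c(files, f)

    f <- paste0(stem, "_densitometry.png")
    grDevices::png(f, width = 900, height = 300)
    plot(dens$x_px, dens$raw, type = "l", col = "grey60",
         xlab = "x (px)", ylab = "mean brightness",
         main = sprintf("%s tube %d densitometry", r$pack_name, r$tube_index))
    lines(dens$x_px, dens$interpolated, col = "blue")
    abline(v = r$mark_x, col = "red", lty = 2)
    points(r$band_x, dens$interpolated[round(r$band_x)], col = "blue", pch = 19)
    dev.off()
    files <- c(files, f)

    sb <- tryCatch(periodogram_sokolove_bushell(pr$interpolated, cal, band_h),
                   racetube_error = function(e) NULL)
    ls_ <- tryCatch(periodogram_lomb_scargle(pr$interpolated, cal, band_h),
                    racetube_error = function(e) NULL)
    cw <- tryCatch(cwt_analysis(pr$interpolated, cal, band_h),
                   racetube_error = function(e) NULL)

    for (sp in list(list(obj = sb, tag = "sokolove_bushell"),
                    list(obj = ls_, tag = "lomb_scargle"))) {
      f <- paste0(stem, "_", sp$tag, ".csv")
      tab <- if (is.null(sp$obj))
        data.frame(period_h = numeric(0), power = numeric(0))
      else data.frame(period_h = sp$obj$periods_h, power = sp$obj$power)
      write.csv(tab, f, row.names = FALSE)
      files <- c(files, f)
      f <- paste0(stem, "_", sp$tag, ".png")
      grDevices::png(f, width = 600, height = 400)
      if (nrow(tab)) {
        plot(tab$period_h, tab$power, type = "l",
             xlab = "period (h)", ylab = "power",
             main = sprintf("%s tube %d %s", r$pack_name, r$tube_index, sp$tag))
        abline(v = sp$obj$peak_period_h, col = "red", lty = 2)
      } else {
        plot.new(); title(main = sprintf("%s: no spectrum", sp$tag))
      }
      dev.off()
      files <- c(files, f)
    }

    f <- paste0(stem, "_cwt.csv")
    if (is.null(cw)) {
      write.csv(data.frame(time_h = numeric(0)), f, row.names = FALSE)
    } else {
      m <- as.data.frame(cw$amplitude)
      names(m) <- sprintf("period_%.3fh", cw$periods_h)
      write.csv(cbind(time_h = cw$times_h, m), f, row.names = FALSE)
    }
    files <- c(files, f)
    f <- paste0(stem, "_cwt.png")
    grDevices::png(f, width = 700, height = 400)
    if (!is.null(cw)) {
      image(cw$times_h, cw$periods_h, cw$amplitude,
            col = grDevices::hcl.colors(64, "viridis"),
            xlab = "time (h)", ylab = "period (h)",
            main = sprintf("%s tube %d CWT amplitude", r$pack_name,
                           r$tube_index))
      acc <- cw$ridge[cw$ridge$accepted, ]
      points(acc$time_h, acc$period_h, pch = ".", col = "white")
    } else {
      plot.new(); title(main = "CWT unavailable (degenerate series)")
    }
    dev.off()
    files <- c(files, f)

    per <- all_periods(r, window = window, band_h = band_h)
    periods_tab <- rbind(periods_tab, data.frame(
      pack = r$pack_name, tube = r$tube_index, method = per$method,
      period_h = per$period_h,
      growth_rate_mm_per_h = r$growth_rate_mm_per_h))
  }
  f <- file.path(outdir, "periods.csv")
  write.csv(periods_tab, f, row.names = FALSE)
  files <- c(files, f)
  inv <- data.frame(file = files,
                    type = ifelse(grepl("\\.csv$", files), "csv", "plot"))
  invisible(inv)
}
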