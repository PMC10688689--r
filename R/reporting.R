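#' Render publication-style tables
#'
#' Writes CSV renditions of the observed cohort dispersal table (wide,
#' one block of tagged/breeding/resident/emigrant columns per colony with
#' a total row), the reappearance table, and — when supplied — the
#' detection and dispersal posterior summaries with rates rounded to 3
#' significant figures.
#'
#' @param tallies List with elements `cohorts` (from [tally_cohorts()] or
#'   [seal_cohorts()]) and optionally `reappearance` (from
#'   [tally_reappearance()]).
#' @param detection_summary Optional data.frame from
#'   [summarize_detection()].
#' @param dispersal_summary Optional named list of data.frames from
#'   [summarize_posterior()], one per direction.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
render_tables <- function(tallies, detection_summary = NULL,
                          dispersal_summary = NULL, dir = ".") {
  if (is.null(tallies$cohorts))
    stop("missing upstream artifact: tallies$cohorts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohorts = file.path(dir, "cohort_dispersal.csv"))
  utils::write.csv(widen_cohorts(tallies$cohorts), paths["cohorts"],
                   row.names = FALSE)
  if (!is.null(tallies$reappearance)) {
    paths["reappearance"] <- file.path(dir, "reappearance.csv")
    utils::write.csv(tallies$reappearance, paths["reappearance"],
                     row.names = FALSE)
  }
  if (!is.null(detection_summary)) {
    d <- detection_summary
    d[c("mean", "lower", "upper")] <-
      lapply(d[c("mean", "lower", "upper")], signif, digits = 3)
    paths["detection"] <- file.path(dir, "detection_estimates.csv")
    utils::write.csv(d, paths["detection"], row.names = FALSE)
  }
  if (!is.null(dispersal_summary)) {
    rows <- lapply(names(dispersal_summary), function(nm) {
      s <- dispersal_summary[[nm]]
      s[c("mean", "lower", "upper")] <-
        lapply(s[c("mean", "lower", "upper")], signif, digits = 3)
      cbind(direction = nm, s)
    })
    paths["dispersal"] <- file.path(dir, "dispersal_estimates.csv")
    utils::write.csv(do.call(rbind, rows), paths["dispersal"],
                     row.names = FALSE)
  }
  invisible(paths)
}

widen_cohorts <- function(tab) {
  if (nrow(tab) == 0) return(data.frame(birth_year = character(0)))
  cols <- unique(tab$colony)
  yrs <- sort(unique(tab$birth_year))
  out <- data.frame(birth_year = c(as.character(yrs), "Total"))
  for (cc in cols) {
    sub <- tab[tab$colony == cc, ]
    sub <- sub[match(yrs, sub$birth_year), ]
    for (v in c("tagged", "breeding", "resident", "emigrant")) {
      val <- sub[[v]]
      out[[paste(cc, v, sep = "_")]] <- c(val, sum(val, na.rm = TRUE))
    }
  }
  out
}

#' Read back a rendered cohort table
#'
#' Inverse of the wide cohort rendition written by [render_tables()]:
#' reconstructs the long-format table with one row per (birth_year,
#' colony).
#'
#' @param path Path to `cohort_dispersal.csv`.
#' @return data.frame with columns `birth_year`, `colony`, `tagged`,
#'   `breeding`, `resident`, `emigrant`.
#' @export
read_cohort_table <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  w <- w[w$birth_year != "Total", , drop = FALSE]
  vars <- c("tagged", "breeding", "resident", "emigrant")
  cols <- unique(sub("_(tagged|breeding|resident|emigrant)$", "",
                     setdiff(names(w), "birth_year")))
  out <- do.call(rbind, lapply(cols, function(cc) {
    d <- data.frame(birth_year = as.integer(w$birth_year), colony = cc)
    for (v in vars) d[[v]] <- as.integer(w[[paste(cc, v, sep = "_")]])
    d
  }))
  rownames(out) <- NULL
  out
}

#' Plot annual dispersal estimates with credible intervals
#'
#' Point-and-interval chart of the posterior per-cohort corrected
#' dispersal rates for one or both directions, with the overall
#' hyper-mean appended as the rightmost point of each series.
#'
#' @param fits Named list of constant-variant `dispersal_fit` objects,
#'   names used as direction labels.
#' @return A ggplot object; its `data` holds one row per plotted
#'   point-interval triple (`direction`, `cohort`, `mean`, `lower`,
#'   `upper`).
#' @export
plot_annual_dispersal <- function(fits) {
  if (inherits(fits, "dispersal_fit")) fits <- list(fit = fits)
  rows <- lapply(names(fits), function(nm) {
    s <- summarize_posterior(fits[[nm]])
    mu <- s[startsWith(s$parameter, "mu_"), ]
    d <- data.frame(direction = nm,
                    cohort = sub("^mu_", "", mu$parameter),
                    mean = mu$mean, lower = mu$lower, upper = mu$upper)
    if ("theta" %in% s$parameter) {
      th <- s[s$parameter == "theta", ]
      d <- rbind(d, data.frame(direction = nm, cohort = "Mean",
                               mean = th$mean, lower = th$lower,
                               upper = th$upper))
    }
    d
  })
  df <- do.call(rbind, rows)
  df$cohort <- factor(df$cohort, levels = unique(df$cohort))
  ggplot2::ggplot(df, ggplot2::aes(x = cohort, y = mean,
                                   colour = direction)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = lower, ymax = upper),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Birth cohort", y = "Natal dispersal rate",
                  colour = "Direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write a reproducibility manifest
#'
#' Records input file digests, the configuration, seeds, and the package
#' version so a run can be repeated exactly.
#'
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param config List of configuration values (coerced to JSON).
#' @param seeds Named or unnamed vector of seeds used.
#' @param path Output JSON path.
#' @return Invisibly, the manifest list.
#' @export
run_manifest <- function(inputs = character(0), config = list(),
                         seeds = integer(0), path) {
  man <- list(
    files = as.list(tools::md5sum(inputs)),
    config = lapply(if (inherits(config, "dispersal_config"))
      unclass(config) else config, unclass),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("colonydisp")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}
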