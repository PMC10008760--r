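#' Read and write the package's CSV formats
#'
#' Long-format, UTF-8, '.'-decimal CSV schemas:
#'
#' * **TAC CSV**: `subject`, `region`, `frame_start_min`, `frame_dur_min`,
#'   `value`, optional `weight`.
#' * **AIF CSV**: `time_min`, `concentration`.
#' * **Parameter CSV**: `subject`, `region`, covariate columns (e.g.
#'   `group`), one `log<param>` column per PK parameter.
#' * **Posterior / result CSV**: `quantity`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `rhat`, `ess` (posterior summaries) or the `univariate_result` columns.
#'
#' Validation failures raise errors with row context.
#'
#' @param path File path.
#' @param x Object to write.
#' @name pumba_io
NULL

#' @rdname pumba_io
#' @return `read_tac_csv` returns a named list of [tac()] objects (one per
#'   subject-region combination).
#' @export
read_tac_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "region", "frame_start_min", "frame_dur_min", "value")
  if (length(setdiff(need, names(d))))
    validation_error("TAC CSV lacks column(s): %s",
                     paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!is.finite(d$frame_dur_min) | d$frame_dur_min <= 0)
  if (length(bad))
    validation_error("nonpositive frame duration at row %d", bad[1] + 1L)
  out <- list()
  for (key in unique(paste(d$subject, d$region, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    dd <- d[d$subject == parts[1] & d$region == parts[2], ]
    dd <- dd[order(dd$frame_start_min), ]
    sch <- frame_schedule(dd$frame_start_min, dd$frame_dur_min)
    w <- if ("weight" %in% names(dd)) dd$weight else NULL
    out[[paste(parts, collapse = ":")]] <-
      tac(sch, dd$value, w, region = parts[2], subject = parts[1])
  }
  out
}

#' @rdname pumba_io
#' @export
write_tac_csv <- function(x, path) {
  if (inherits(x, "tac")) x <- list(x)
  if (is.data.frame(x)) {
    write.csv(x, path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(x, function(tc)
    data.frame(subject = tc$subject, region = tc$region,
               frame_start_min = tc$schedule$start,
               frame_dur_min = tc$schedule$dur,
               value = tc$values, weight = tc$weights))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pumba_io
#' @export
read_aif_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("time_min", "concentration"), names(d))))
    validation_error("AIF CSV needs columns time_min, concentration")
  aif(d$time_min, d$concentration)
}

#' @rdname pumba_io
#' @export
write_aif_csv <- function(x, path) {
  write.csv(data.frame(time_min = x$time, concentration = x$conc), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pumba_io
#' @export
read_parameter_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("subject", "region"), names(d))))
    validation_error("parameter CSV needs subject and region columns")
  if (!any(grepl("^log", names(d))))
    validation_error("parameter CSV has no log<param> columns")
  if ("group" %in% names(d))
    d$group <- factor(d$group, levels = sort(unique(d$group)))
  tibble::as_tibble(d)
}

#' @rdname pumba_io
#' @export
write_parameter_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pumba_io
#' @export
write_posterior_csv <- function(x, path) {
  if (inherits(x, "pumba_fit")) x <- x$summary
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the seed(s), configuration and software versions of a stochastic
#' run as JSON next to its outputs.
#'
#' @param path Output path (JSON).
#' @param seed Master seed.
#' @param config Arbitrary configuration list (serialised as-is).
#' @param extra Optional named list merged into the manifest.
#' @export
write_manifest <- function(path, seed, config = NULL, extra = list()) {
  manifest <- c(list(seed = seed,
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("pumba")),
                     created = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                     config = config),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
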