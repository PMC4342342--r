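#' Write a metric signal to CSV or JSON
#'
#' The CSV form has columns `bin_left_edge`, `count`, `value`, preceded by
#' `#`-prefixed comment lines embedding the parameters that produced the
#' signal (kind, bin count, n, rho, R, R_A, and subsampling metadata where
#' relevant), so every output file is self-describing. The JSON form holds
#' the full metadata and all bin columns.
#'
#' @param signal a [colony_signal].
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path, format = NULL) {
  stopifnot(inherits(signal, "colony_signal"))
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  meta <- signal_meta(signal)
  if (format == "json") {
    jsonlite::write_json(
      list(meta = meta,
           bins = as.data.frame(signal[, c("bin", "left_edge", "midpoint",
                                           "count", "expected", "value")])),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  flat <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(sprintf("# %s = %s", names(flat),
                     vapply(flat, function(v) paste(format(v, digits = 15), collapse = ","), "")),
             con)
  out <- data.frame(bin_left_edge = signal$left_edge, count = signal$count,
                    value = signal$value)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read back a signal CSV written by [write_signal()]
#'
#' @param path a CSV path.
#' @return a tibble with columns `bin_left_edge`, `count`, `value`.
#' @export
read_signal_csv <- function(path) {
  as_tibble(read.csv(path, comment.char = "#"))
}

#' Write an angular spectrum to CSV
#'
#' Columns: `k`, `re`, `im`, `modulus`, `power`.
#'
#' @param spectrum an [angular_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  write.csv(as.data.frame(spectrum[, c("k", "re", "im", "modulus", "power")]),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` assignment per line; blank lines and `#` comments are
#' ignored; values that parse as numbers become numeric, comma-separated
#' values become vectors.
#'
#' @param path configuration file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) abort(sprintf("config line without '=': %s", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  setNames(vals, keys)
}

pipeline_defaults <- function() {
  list(L = 180, M = 200, N = 200, n_s = 1000, persistence = 3,
       seed = 1, length_scale = 1, fit_degree = 6)
}

#' Run the full analysis workflow over a set of colonies
#'
#' Drives the complete pipeline — grids in, per-colony metric signals and
#' index records out, plus a sample summary when at least two colonies
#' share time points — writing everything under `out_dir`:
#' \itemize{
#'   \item `signals/<colony>_<t>_{radial,angular,pair}.csv` and
#'     `_spectrum.csv` per colony and time,
#'   \item `indices.csv` (one row per colony and time),
#'   \item `summary.csv` and `summary.json` (per-time means and SEM),
#'   \item `run_log.txt` recording package version, parameters, seeds and
#'     per-colony diagnostics.
#' }
#'
#' Input is named by `config` (a list, or a path parsed by
#' [read_config()]): either `masks` (character vector of mask paths, one
#' colony each), `dataset` (a 4-D container path), `grids` (an in-memory
#' tibble with `colony`, `t`, `grid`), or `synthetic = "csr_disks"` with
#' `n_colonies`, `rho`, `R`. Analysis parameters `L`, `M`, `N`, `n_s`,
#' `persistence`, `seed`, `length_scale` default to `L = 180`, `M = 200`,
#' `N = 200`, `n_s = 1000`, `persistence = 3`.
#'
#' A failure while analysing one colony is logged and reported; remaining
#' colonies are still processed.
#'
#' @param config a named list or a config file path.
#' @param out_dir output directory (created if needed).
#' @return the index-record tibble, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig_dir <- file.path(out_dir, "signals")
  dir.create(sig_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("colonymetrics %s", as.character(utils::packageVersion("colonymetrics"))),
    sprintf("run at %s", format(Sys.time())),
    sprintf("parameters: L=%s M=%s N=%s n_s=%s persistence=%s seed=%s length_scale=%s",
            cfg$L, cfg$M, cfg$N, cfg$n_s, cfg$persistence, cfg$seed, cfg$length_scale)
  )

  grids <- pipeline_inputs(cfg)
  records <- list()
  for (i in seq_len(nrow(grids))) {
    colony <- grids$colony[[i]]; t <- grids$t[[i]]; grid <- grids$grid[[i]]
    tag <- sprintf("%s_%s", colony, format(t))
    res <- tryCatch({
      rec <- analyze_colony(grid, L = cfg$L, M = cfg$M, N = cfg$N,
                            n_s = cfg$n_s, persistence = cfg$persistence,
                            seed = cfg$seed + i, t = t)
      rad <- radial_metric(grid, cfg$L)
      write_signal(rad, file.path(sig_dir, paste0(tag, "_radial.csv")))
      R_csr_lattice <- rec$R_csr / grid$length_scale
      if (!rec$annulus_empty) {
        ann <- extract_annulus(grid, max(R_csr_lattice, 1e-9))
        ang <- angular_metric(ann, cfg$M)
        write_signal(ang, file.path(sig_dir, paste0(tag, "_angular.csv")))
        write_spectrum(angular_spectrum(ang),
                       file.path(sig_dir, paste0(tag, "_spectrum.csv")))
        use_ns <- if (ann$n <= max(cfg$n_s, 5000)) "all" else cfg$n_s
        pc <- pair_correlation_metric(ann, cfg$N, n_s = use_ns, seed = cfg$seed + i)
        write_signal(pc, file.path(sig_dir, paste0(tag, "_pair.csv")))
      }
      log_lines <- c(log_lines, sprintf(
        "colony %s t=%s: n=%d rho=%.5f R=%.2f R_csr=%.2f%s",
        colony, format(t), rec$n, rec$rho, rec$R, rec$R_csr,
        if (rec$annulus_empty) " [empty annulus: I_theta = I_Theta = 0]" else ""))
      dplyr::bind_cols(tibble(colony = colony), rec)
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("colony %s t=%s: ERROR %s",
                                         colony, format(t), conditionMessage(e)))
      warn(sprintf("colony %s at t=%s failed: %s", colony, format(t),
                   conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) records[[length(records) + 1L]] <- res
  }
  if (length(records) == 0L) {
    writeLines(log_lines, log_path)
    abort("pipeline produced no index records")
  }
  records <- dplyr::bind_rows(records)
  write.csv(records, file.path(out_dir, "indices.csv"), row.names = FALSE)

  summary_ok <- tryCatch({
    degree <- if (length(unique(records$t)) > cfg$fit_degree) cfg$fit_degree else NA
    summ <- summarize_sample(records, fit_degree = degree)
    write.csv(tidy(summ), file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(parameters = cfg[c("L", "M", "N", "n_s", "persistence", "seed",
                              "length_scale")],
           summary = as.data.frame(tidy(summ))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) {
    log_lines <<- c(log_lines, sprintf("summary skipped: %s", conditionMessage(e)))
    FALSE
  })
  if (!summary_ok) inform("sample summary not written (single colony or mismatched times)")
  writeLines(log_lines, log_path)
  invisible(records)
}

# Resolve the configured input source into a (colony, t, grid) tibble.
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$grids)) {
    return(as_tibble(cfg$grids))
  }
  if (!is.null(cfg$masks)) {
    missing <- !file.exists(cfg$masks)
    if (any(missing)) abort(sprintf("mask file not found: %s", cfg$masks[missing][1]))
    grids <- purrr::imap(cfg$masks, function(p, i) {
      m <- read_mask(p)
      grid_from_matrix(m, length_scale = cfg$length_scale)
    })
    return(tibble(colony = tools::file_path_sans_ext(basename(cfg$masks)),
                  t = NA_real_, grid = grids))
  }
  if (!is.null(cfg$dataset)) {
    ds <- read_dataset4d(cfg$dataset, length_scale = cfg$length_scale)
    return(grids_from_dataset4d(ds))
  }
  if (identical(cfg$synthetic, "csr_disks")) {
    n_col <- cfg$n_colonies %||% 10
    grids <- purrr::map(seq_len(n_col), function(i) {
      random_disk(cfg$rho %||% 0.1, cfg$R %||% 150, seed = cfg$seed + i)
    })
    return(tibble(colony = seq_len(n_col), t = 0, grid = grids))
  }
  abort("config must name an input: masks, dataset, grids, or synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
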