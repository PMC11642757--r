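#' Write a posterior to disk as plain text
#'
#' Serialises an [run_abc()] result as two files under `dir`: a
#' tab-separated particle table (`particles.tsv`: meiotic, mitotic,
#' distance, weight) and a `key: value` metadata file (`run_meta.txt`:
#' configuration echo, seed, tolerance and acceptance histories).
#' [read_posterior()] restores an `abc_posterior` usable by every
#' downstream function.
#'
#' @param posterior An `abc_posterior`.
#' @param dir Output directory (created if missing).
#' @return `write_posterior()` returns `dir` invisibly; `read_posterior()`
#'   an `abc_posterior`.
#' @export
write_posterior <- function(posterior, dir) {
  if (!inherits(posterior, "abc_posterior")) {
    stop("`posterior` must be an abc_posterior.", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_six(posterior$particles, file.path(dir, "particles.tsv"))
  meta <- c(
    n_iterations = as.character(posterior$n_iterations),
    tolerance_history = paste(format(posterior$tolerance_history,
                                     digits = 6), collapse = ","),
    p_acc_history = paste(format(posterior$p_acc_history, digits = 6),
                          collapse = ","),
    target = paste(format(posterior$target, digits = 6), collapse = ","),
    seed = if (is.null(posterior$seed)) "NA"
           else as.character(posterior$seed)
  )
  if (!is.null(posterior$control)) {
    meta <- c(
      meta,
      n_particles = as.character(posterior$control$n_particles),
      keep_fraction = as.character(posterior$control$keep_fraction),
      p_acc_min = as.character(posterior$control$p_acc_min),
      n_embryos_per_trial =
        as.character(posterior$control$n_embryos_per_trial)
    )
  }
  writeLines(paste0(names(meta), ": ", meta),
             file.path(dir, "run_meta.txt"))
  if (!is.null(posterior$model_config)) {
    write_model_config(posterior$model_config,
                       file.path(dir, "model_config.txt"))
  }
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(dir) {
  particles <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "particles.tsv"))
  )
  meta_path <- file.path(dir, "run_meta.txt")
  meta <- if (file.exists(meta_path)) read_key_value(meta_path) else c()
  split_num <- function(key) {
    if (!key %in% names(meta) || !nzchar(meta[[key]])) return(numeric(0))
    as.numeric(strsplit(meta[[key]], ",", fixed = TRUE)[[1]])
  }
  cfg_path <- file.path(dir, "model_config.txt")
  structure(
    list(
      particles = dplyr::mutate(particles,
                                weight = .data$weight / sum(.data$weight)),
      tolerance_history = split_num("tolerance_history"),
      p_acc_history = split_num("p_acc_history"),
      n_iterations = if ("n_iterations" %in% names(meta)) {
        as.integer(meta[["n_iterations"]])
      } else NA_integer_,
      target = split_num("target"),
      control = NULL,
      model_config = if (file.exists(cfg_path)) {
        read_model_config(cfg_path)
      } else NULL,
      seed = if (identical(meta[["seed"]], "NA")) NULL
             else as.integer(meta[["seed"]])
    ),
    class = "abc_posterior"
  )
}

#' Record a run manifest
#'
#' Writes a `key: value` manifest capturing what produced an output
#' directory: the command label, a flat echo of configuration fields, the
#' seed, start/end timestamps, the package version and the output file
#' list. Re-running the same command with the same seed and configuration
#' reproduces the tabular outputs byte for byte.
#'
#' @param path Manifest file path.
#' @param command Short label for the pipeline stage.
#' @param config Named list (or vector) of configuration fields to echo.
#' @param seed Seed used (or `NA`).
#' @param outputs Character vector of files the run wrote.
#' @param started,finished POSIXct timestamps (default both `Sys.time()`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NA,
                               outputs = character(0),
                               started = Sys.time(), finished = Sys.time()) {
  fields <- c(
    command = command,
    seed = as.character(seed),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("mosaicabc"))
  )
  cfg <- unlist(config)
  if (length(cfg)) {
    names(cfg) <- paste0("config.", names(cfg))
    fields <- c(fields, vapply(cfg, format, ""))
  }
  if (length(outputs)) {
    fields <- c(fields, outputs = paste(outputs, collapse = ","))
  }
  writeLines(paste0(names(fields), ": ", fields), path)
  invisible(path)
}

# TSV with a single header row; floats at 6 significant digits
write_tsv_six <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a predictive sample or tables as tab-separated files
#'
#' `write_predictive_tables()` writes each table of a
#' [predictive_tables()] result as `<name>.tsv` under `dir`, including the
#' ribbon-plot-ready long rebiopsy table (first class, second class, embryo
#' type, count).
#'
#' @param tables A `predictive_tables` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_predictive_tables <- function(tables, dir) {
  if (!inherits(tables, "predictive_tables")) {
    stop("`tables` must come from predictive_tables().", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("embryo_types", "aneuploid_fraction", "biopsy_by_embryo",
                 "rebiopsy", "concordance")) {
    write_tsv_six(tables[[name]], file.path(dir, paste0(name, ".tsv")))
  }
  invisible(dir)
}
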