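# File formats (plain, diff-able TSV throughout) and the end-to-end
# pipeline driver.

fmt_num <- function(x) {
  # full-precision, locale-independent numbers so write -> read -> write
  # reproduces files byte for byte
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a connectivity matrix as TSV
#'
#' Full-precision TSV with region names as header row and first column, so
#' that write / read / write reproduces the file exactly.
#'
#' @param matrix A `conn_matrix` (or any named square matrix).
#' @param path Output file.
#' @export
write_conn_matrix <- function(matrix, path) {
  df <- data.frame(region = rownames(matrix),
                   matrix(fmt_num(matrix), nrow(matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region", colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a connectivity matrix written by [write_conn_matrix()]
#'
#' @param path TSV path.
#' @return A `conn_matrix`.
#' @export
read_conn_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  structure(m, class = c("conn_matrix", class(m)),
            subject_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write ROI time series as TSV
#'
#' One header row of region names, one row per frame, full precision.
#'
#' @param ts A `roi_ts`.
#' @param path Output file.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(apply(ts$data, 2, fmt_num), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a directory of per-subject ROI time-series files
#'
#' Each delimited file holds one subject: a header row of region names and
#' one row per frame. All files must contain the same region set; columns
#' are realigned to the first file's order (with a warning) if a file lists
#' them in a different order. Subject ids come from file names.
#'
#' @param path Directory of `.tsv` / `.csv` / `.txt` files.
#' @param sampling_interval Seconds per frame (default 2).
#' @return List of `roi_ts`, in file-name order.
#' @export
read_timeseries_dir <- function(path, sampling_interval = 2) {
  files <- sort(list.files(path, pattern = "\\.(tsv|csv|txt)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no time-series files found in ", path)
  out <- vector("list", length(files))
  ref <- NULL
  for (k in seq_along(files)) {
    sep <- if (grepl("\\.csv$", files[k])) "," else "\t"
    df <- utils::read.table(files[k], header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character")
    m <- as.matrix(df)
    vals <- suppressWarnings(as.numeric(m))
    if (anyNA(vals)) {
      bad <- which(is.na(matrix(vals, nrow(m))), arr.ind = TRUE)[1, ]
      stop("non-numeric value in ", basename(files[k]), " at row ",
           bad[1], ", column '", colnames(m)[bad[2]], "'")
    }
    m <- matrix(vals, nrow(m), dimnames = dimnames(m))
    if (is.null(ref)) {
      ref <- colnames(m)
    } else if (!setequal(colnames(m), ref)) {
      stop("region header of ", basename(files[k]),
           " does not match ", basename(files[1]))
    } else if (!identical(colnames(m), ref)) {
      warning("realigning columns of ", basename(files[k]),
              " to match ", basename(files[1]))
      m <- m[, ref, drop = FALSE]
    }
    out[[k]] <- roi_timeseries(m, sub("\\.[^.]*$", "", basename(files[k])),
                               sampling_interval)
  }
  out
}

#' Read a per-subject covariate table
#'
#' @param path Delimited file with a header; must contain `subject_id` and
#'   `group` columns.
#' @return Data.frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df))) {
    stop("covariate table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Pipeline run configuration
#'
#' Collects every tunable of [run_full_pipeline()] in one list that
#' round-trips losslessly through YAML or JSON and is echoed into the run
#' manifest.
#'
#' @param simulate NULL, or a list of [sim_config()] arguments (minus
#'   `partition` and `seed`) to generate the input study instead of reading
#'   files.
#' @param series_dir,covariates_file Input paths when not simulating.
#' @param partition_file Optional partition TSV; NULL = packaged default.
#' @param discard_frames Leading frames to drop from read series
#'   (default 10).
#' @param band Band-pass edges in Hz, `c(low, high)`; NULL skips filtering
#'   (simulated series are already band-free white noise).
#' @param mask_alpha,t_threshold,p_threshold,tails,n_perm As in
#'   [nbs_run()].
#' @param fwe_alpha Component significance level (default 0.05).
#' @param variables Clinical variables for the association stage.
#' @param seed Integer master seed.
#' @param out_dir Output directory for the results bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, series_dir = NULL,
                       covariates_file = NULL, partition_file = NULL,
                       discard_frames = 10, band = c(0.01, 0.08),
                       mask_alpha = 0.05, t_threshold = 3,
                       p_threshold = NULL, tails = "both", n_perm = 1000,
                       fwe_alpha = 0.05,
                       variables = c("FPG", "PG2h", "HbA1c", "HOMA_IR",
                                     "MoCA"),
                       seed = 42, out_dir = "results") {
  structure(list(simulate = simulate, series_dir = series_dir,
                 covariates_file = covariates_file,
                 partition_file = partition_file,
                 discard_frames = discard_frames, band = band,
                 mask_alpha = mask_alpha, t_threshold = t_threshold,
                 p_threshold = p_threshold, tails = tails, n_perm = n_perm,
                 fwe_alpha = fwe_alpha, variables = variables, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file of [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, lst)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full connectome analysis pipeline
#'
#' Orchestrates every stage in order: input (simulated study or series
#' files through preprocessing and connectivity), NBS with permutation FWE
#' control, edge-pattern classification of significant components,
#' network-level strength comparison, and clinical associations. Writes a
#' results bundle (TSV tables, null distribution, JSON manifest carrying
#' the config and its hash) atomically: nothing is written unless every
#' stage succeeds. Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the in-memory results list (study, nbs, patterns,
#'   network_level, associations, manifest).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  partition <- stage("partition", {
    if (is.null(config$partition_file)) default_partition()
    else read_partition(config$partition_file)
  })
  study <- stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config,
                     c(config$simulate,
                       list(partition = partition, seed = config$seed)))
      generate_study(cfg, keep_timeseries = FALSE)$study
    } else {
      ts <- read_timeseries_dir(config$series_dir)
      if (config$discard_frames > 0) {
        ts <- lapply(ts, discard_frames, n = config$discard_frames)
      }
      if (!is.null(config$band)) {
        ts <- lapply(ts, bandpass_chebyshev, low_hz = config$band[1],
                     high_hz = config$band[2])
      }
      cov <- read_covariates(config$covariates_file)
      ids <- vapply(ts, `[[`, "", "subject_id")
      cov <- cov[match(ids, cov$subject_id), ]
      group_study(lapply(ts, pearson_connectivity),
                  factor(cov$group, levels = c("control", "patient")),
                  covariates = cov)
    }
  })
  nbs <- stage("nbs", nbs_run(
    study, mask_alpha = config$mask_alpha, t_threshold = config$t_threshold,
    p_threshold = config$p_threshold, tails = config$tails,
    n_perm = config$n_perm, seed = config$seed))
  sig <- Filter(function(cp) cp$p_fwe < config$fwe_alpha, nbs$components)
  patterns <- stage("patterns", {
    if (length(sig) == 0) NULL else {
      stats <- edge_t_tests(study, nbs$mask)
      recs <- do.call(rbind, lapply(sig, function(cp) {
        e <- cp$edges
        ia <- match(e$region_a, study$regions)
        ib <- match(e$region_b, study$regions)
        e$mean_patient <- stats$mean_patient[cbind(ia, ib)]
        e$mean_control <- stats$mean_control[cbind(ia, ib)]
        e$p_fwe <- cp$p_fwe
        e
      }))
      recs$pattern <- classify_edge(recs$mean_patient, recs$mean_control)
      annotate_between_within(recs, partition)
    }
  })
  network_level <- stage("network_level",
                         compare_network_strengths(study, partition))
  associations <- stage("associations", {
    have <- if (is.null(study$covariates)) character() else {
      intersect(config$variables, names(study$covariates))
    }
    if (is.null(patterns) || length(have) == 0) NULL else {
      edge_clinical_associations(
        study, unique(patterns[, c("region_a", "region_b")]), have)
    }
  })
  manifest <- list(package = "fcnbs",
                   version = as.character(utils::packageVersion("fcnbs")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   n_components = length(nbs$components),
                   n_significant = length(sig))

  stage("write", {
    staging <- tempfile("fcnbs_bundle_")
    dir.create(staging)
    comp_df <- if (length(nbs$components) > 0) {
      do.call(rbind, lapply(seq_along(nbs$components), function(k) {
        cp <- nbs$components[[k]]
        data.frame(component = k, tail = cp$tail, size = cp$size,
                   p_fwe = cp$p_fwe, cp$edges, stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(component = integer(), tail = character(),
                 size = integer(), p_fwe = numeric(), region_a = character(),
                 region_b = character(), t = numeric(), p = numeric())
    }
    write_tsv_plain(comp_df, file.path(staging, "components.tsv"))
    for (tl in names(nbs$runs)) {
      writeLines(as.character(nbs$runs[[tl]]$null_max_sizes),
                 file.path(staging, paste0("null_max_sizes_", tl, ".txt")))
    }
    if (!is.null(patterns)) {
      pc <- count_patterns(patterns)
      write_tsv_plain(patterns, file.path(staging, "edge_patterns.tsv"))
      write_tsv_plain(data.frame(pattern = names(pc),
                                 count = as.integer(pc)),
                      file.path(staging, "pattern_counts.tsv"))
    }
    write_tsv_plain(network_level, file.path(staging, "network_level.tsv"))
    if (!is.null(associations)) {
      write_tsv_plain(associations, file.path(staging, "associations.tsv"))
    }
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(staging, "manifest.json"))
    if (dir.exists(config$out_dir)) {
      unlink(config$out_dir, recursive = TRUE)
    }
    dir.create(dirname(config$out_dir), recursive = TRUE,
               showWarnings = FALSE)
    if (!file.rename(staging, config$out_dir)) {
      # cross-device fallback
      dir.create(config$out_dir, recursive = TRUE)
      file.copy(list.files(staging, full.names = TRUE), config$out_dir)
      unlink(staging, recursive = TRUE)
    }
  })
  invisible(list(study = study, nbs = nbs, patterns = patterns,
                 network_level = network_level,
                 associations = associations, manifest = manifest))
}
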