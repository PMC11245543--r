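# Pipeline tying the stages into the three tracer tracks:
# 13C-glucose water-soluble metabolites (serum-normalized), 2H-serine
# NADP+/NADPH active-H deconvolution, and D2O fatty-acid labeling.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
    cfg$.base_dir <- dirname(normalizePath(config))
    cfg$.config_path <- normalizePath(config)
    cfg
  } else if (is.list(config)) {
    if (is.null(config$.base_dir)) config$.base_dir <- getwd()
    config
  } else stop("config must be a file path or a list")
}

resolve_path <- function(path, base) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
}

validate_run_config <- function(cfg) {
  errs <- character(0)
  if (is.null(cfg$tracks) || !length(cfg$tracks) || is.null(names(cfg$tracks)))
    errs <- c(errs, "config must define a named 'tracks' list")
  known_types <- c("watersoluble", "nadph", "fatty_acid")
  for (nm in names(cfg$tracks)) {
    tr <- cfg$tracks[[nm]]
    if (is.null(tr$peaks)) {
      errs <- c(errs, sprintf("track '%s': missing 'peaks' file", nm))
    } else if (!file.exists(resolve_path(tr$peaks, cfg$.base_dir))) {
      errs <- c(errs, sprintf("track '%s': peaks file not found: %s", nm, tr$peaks))
    }
    if (is.null(tr$type) || !tr$type %in% known_types)
      errs <- c(errs, sprintf("track '%s': type must be one of %s", nm,
                              paste(known_types, collapse = ", ")))
    if (is.null(tr$tracer$element) || !tr$tracer$element %in% c("C", "H"))
      errs <- c(errs, sprintf("track '%s': tracer element must be C or H", nm))
  }
  if (!is.null(cfg$serum)) {
    if (is.null(cfg$serum$peaks)) {
      errs <- c(errs, "serum: missing 'peaks' file")
    } else if (!file.exists(resolve_path(cfg$serum$peaks, cfg$.base_dir))) {
      errs <- c(errs, paste0("serum: peaks file not found: ", cfg$serum$peaks))
    }
  }
  if (!is.null(cfg$samples) &&
      !file.exists(resolve_path(cfg$samples, cfg$.base_dir)))
    errs <- c(errs, paste0("samples file not found: ", cfg$samples))
  for (nm in names(cfg$assays)) {
    if (!file.exists(resolve_path(cfg$assays[[nm]], cfg$.base_dir)))
      errs <- c(errs, sprintf("assay '%s': file not found: %s", nm, cfg$assays[[nm]]))
  }
  if (length(errs))
    stop("invalid pipeline configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(cfg)
}

# correct every compound of one peak table; returns corrected MIDs and
# labeling metrics in long format
correct_track <- function(pt, tracer_element, purity, mode, meta, track_name) {
  corrected <- NULL
  metrics <- NULL
  mids <- list()
  for (cmp in names(pt$compounds)) {
    cc <- pt$compounds[[cmp]]
    if (!is.na(cc$element) && cc$element != tracer_element)
      stop("track ", sQuote(track_name), ": compound ", sQuote(cmp),
           " is tagged for tracer element ", cc$element,
           " but the track declares ", tracer_element)
    f <- parse_formula(cc$formula)
    if (!tracer_element %in% names(f))
      stop("track ", sQuote(track_name), ": tracer element ", tracer_element,
           " absent from formula of ", sQuote(cmp))
    n_label <- min(nrow(cc$intensities) - 1L, f[[tracer_element]])
    cm <- build_correction_matrix(f, tracer_spec(tracer_element, n_label, purity),
                                  max_shift = nrow(cc$intensities) - 1L, mode = mode)
    mids[[cmp]] <- list()
    for (s in pt$samples) {
      raw <- cc$intensities[, s]
      if (all(raw == 0)) {
        warning("track ", sQuote(track_name), ": all-zero intensities for ",
                sQuote(cmp), " in sample ", sQuote(s), "; skipped")
        next
      }
      fit <- correct_intensities(raw, cm)
      mids[[cmp]][[s]] <- fit$fractions
      corrected <- rbind(corrected, data.frame(
        track = track_name, compound = cmp, sample = s,
        shift = seq_along(fit$fractions) - 1L, fraction = unname(fit$fractions),
        residual_norm = fit$residual_norm, raw_total = fit$raw_total,
        stringsAsFactors = FALSE))
      lm_ <- labeling_metrics(fit$fractions, n_label)
      metrics <- rbind(metrics, data.frame(
        track = track_name, compound = cmp, sample = s,
        group = if (!is.null(meta$group)) meta$group[match(s, meta$sample)]
                else NA_character_,
        n_atoms = n_label,
        labeled_fraction = lm_$labeled_fraction,
        fractional_enrichment = lm_$fractional_enrichment,
        stringsAsFactors = FALSE))
    }
  }
  list(corrected = corrected, metrics = metrics, mids = mids)
}

process_assays <- function(cfg) {
  out <- NULL
  rd <- function(nm) utils::read.csv(resolve_path(cfg$assays[[nm]], cfg$.base_dir),
                                     stringsAsFactors = FALSE)
  add <- function(assay, group, key, value) {
    rbind(out, data.frame(assay = assay, group = group, key = as.character(key),
                          value = value, stringsAsFactors = FALSE))
  }
  if (!is.null(cfg$assays$serine_consumption)) {
    df <- rd("serine_consumption")
    for (g in unique(df$group)) {
      sub <- df[df$group == g, ]
      base <- sub[sub$timepoint_h == 0, ]
      if (!nrow(base)) stop("serine consumption assay: no 0-hour rows for group ", g)
      a0 <- mean(base$serine_ug); c0 <- mean(base$cells)  # duplicate wells: mean
      for (t in setdiff(sort(unique(sub$timepoint_h)), 0)) {
        tp <- sub[sub$timepoint_h == t, ]
        out <- add("serine_consumption_ug_per_1e6_cells", g, t,
                   serine_consumption(a0, mean(tp$serine_ug), c0, mean(tp$cells)))
      }
    }
  }
  if (!is.null(cfg$assays$ros)) {
    df <- rd("ros")
    vals <- ros_level(df$f_stained, df$f_unstained, df$cells_millions)
    for (i in seq_len(nrow(df)))
      out <- add("ros_au_per_1e6_cells", df$group[i], df$well[i], vals[i])
  }
  if (!is.null(cfg$assays$proliferation)) {
    df <- rd("proliferation")
    for (g in unique(df$group)) for (w in unique(df$well[df$group == g])) {
      sub <- df[df$group == g & df$well == w, ]
      out <- add("confluence_slope_pct_per_h", g, w,
                 proliferation_slope(sub$time_h, sub$confluence_pct))
    }
  }
  if (!is.null(cfg$assays$redox)) {
    df <- rd("redox")
    for (i in seq_len(nrow(df))) {
      out <- add("nadph_nadp_ratio", df$group[i], df$replicate[i],
                 redox_ratio(df$nadph[i], df$nadp[i]))
      out <- add("gsh_gssg_ratio", df$group[i], df$replicate[i],
                 redox_ratio(df$gsh[i], df$gssg[i]))
    }
  }
  if (!is.null(cfg$assays$h2o2)) {
    df <- rd("h2o2")
    for (g in unique(df$group)) {
      sub <- df[df$group == g, ]
      ctrl <- sub$count[sub$dose_umol_l == 0]
      if (!length(ctrl)) stop("H2O2 assay: no untreated wells for group ", g)
      for (d in setdiff(sort(unique(sub$dose_umol_l)), 0)) {
        rel <- relative_proliferation(sub$count[sub$dose_umol_l == d], ctrl)
        out <- add("relative_proliferation", g, d, mean(rel))
      }
    }
  }
  out
}

#' Run the full tracing pipeline from a configuration file
#'
#' Executes correct -> metrics -> (serum normalization | active-H
#' deconvolution | fatty-acid labeling) for each configured track and writes
#' tidy CSV outputs plus a run log. The configuration is a YAML file (all
#' paths relative to its directory) with entries:
#'
#' * `output_dir` — where outputs are written;
#' * `mode` — `"high_res"` (default) or `"nominal"`;
#' * `seed` — recorded in the log (the pipeline itself is deterministic);
#' * `samples` — CSV with `sample`, `group`, `mouse_id` (and optionally a
#'   `serum_enrichment` fallback column);
#' * `serum` — peak table of serum glucose plus `compound` and
#'   `denominator` (`"fractional_enrichment"`, the default, or
#'   `"mplus_fraction"` for the fully-labeled M+n fraction);
#' * `tracks` — named list; each has `peaks`, `tracer` (`element`,
#'   `purity`), and `type`: `"watersoluble"` (optionally
#'   `normalize_to_serum: true` and `metric:` `"labeled_fraction"` (default)
#'   or `"fractional_enrichment"`), `"nadph"` (with `nadp_compound`,
#'   `nadph_compound`), or `"fatty_acid"` (with an `essential` name list);
#' * `assays` — optional named CSV paths (`serine_consumption`, `ros`,
#'   `proliferation`, `redox`, `h2o2`).
#'
#' Configuration problems are reported before any computation. Outputs:
#' `corrected_mids.csv`, `labeling_metrics.csv`, `normalized_enrichment.csv`,
#' `active_h.csv`, `active_h_summary.csv`, `assays.csv`, `run.log`. Reruns
#' on identical inputs produce identical outputs.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, an object of class `pipeline_run` with the assembled
#'   tables and output paths.
#' @seealso [write_sim_cohort()], which emits a ready-to-run configuration.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("config must name an output_dir")
  if (is.null(cfg$mode)) cfg$mode <- "high_res"
  validate_run_config(cfg)
  out_dir <- resolve_path(cfg$output_dir, cfg$.base_dir)
  if (!is.null(output_dir)) out_dir <- output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  meta <- if (!is.null(cfg$samples)) {
    utils::read.csv(resolve_path(cfg$samples, cfg$.base_dir),
                    stringsAsFactors = FALSE)
  } else data.frame(sample = character(0), group = character(0),
                    mouse_id = character(0), stringsAsFactors = FALSE)
  if (!"mouse_id" %in% names(meta)) meta$mouse_id <- meta$sample

  # serum reference first: per-mouse tracer-enrichment denominator
  serum <- NULL
  if (!is.null(cfg$serum)) {
    pt <- read_peak_table(resolve_path(cfg$serum$peaks, cfg$.base_dir))
    purity <- if (is.null(cfg$serum$tracer$purity)) 1 else cfg$serum$tracer$purity
    el <- if (is.null(cfg$serum$tracer$element)) "C" else cfg$serum$tracer$element
    res <- correct_track(pt, el, purity, cfg$mode, meta, ".serum")
    cmp <- if (is.null(cfg$serum$compound)) names(res$mids)[1L] else cfg$serum$compound
    if (!cmp %in% names(res$mids))
      stop("serum compound ", sQuote(cmp), " absent from serum peak table")
    denom_kind <- if (is.null(cfg$serum$denominator)) "fractional_enrichment"
                  else cfg$serum$denominator
    serum <- do.call(rbind, lapply(names(res$mids[[cmp]]), function(s) {
      m <- res$mids[[cmp]][[s]]
      val <- switch(denom_kind,
        fractional_enrichment = labeling_metrics(m, length(m) - 1L)$fractional_enrichment,
        mplus_fraction = unname(m[length(m)]),
        stop("unknown serum denominator: ", denom_kind))
      data.frame(sample = s,
                 mouse_id = if (s %in% meta$sample) meta$mouse_id[match(s, meta$sample)] else s,
                 serum_enrichment = val, stringsAsFactors = FALSE)
    }))
  } else if ("serum_enrichment" %in% names(meta)) {
    serum <- meta[, c("sample", "mouse_id", "serum_enrichment")]
  }

  corrected <- NULL; metrics <- NULL; normalized <- NULL
  active_h <- NULL; essential_flags <- NULL
  for (nm in names(cfg$tracks)) {
    tr <- cfg$tracks[[nm]]
    pt <- read_peak_table(resolve_path(tr$peaks, cfg$.base_dir))
    purity <- if (is.null(tr$tracer$purity)) 1 else tr$tracer$purity
    res <- correct_track(pt, tr$tracer$element, purity, cfg$mode, meta, nm)
    corrected <- rbind(corrected, res$corrected)
    m <- res$metrics
    if (tr$type == "fatty_acid") {
      ess <- unlist(tr$essential)
      m$essential <- m$compound %in% ess
    }
    metrics <- rbind(metrics, merge_cols(m))
    if (tr$type == "watersoluble" && isTRUE(tr$normalize_to_serum)) {
      if (is.null(serum))
        stop("track ", sQuote(nm), " requests serum normalization but no serum ",
             "reference or serum_enrichment metadata is configured")
      metric_kind <- if (is.null(tr$metric)) "labeled_fraction" else tr$metric
      for (i in seq_len(nrow(m))) {
        mouse <- if (m$sample[i] %in% meta$sample)
          meta$mouse_id[match(m$sample[i], meta$sample)] else m$sample[i]
        j <- match(mouse, serum$mouse_id)
        if (is.na(j))
          stop("no serum enrichment for mouse ", sQuote(mouse),
               " (unmatched pairing)")
        nr <- normalize_to_serum(m[[metric_kind]][i], serum$serum_enrichment[j], mouse)
        normalized <- rbind(normalized, data.frame(
          track = nm, compound = m$compound[i], sample = m$sample[i],
          group = m$group[i], mouse_id = mouse, metric = metric_kind,
          tumor_metric = nr$tumor_metric, serum_enrichment = nr$serum_enrichment,
          value = nr$value, stringsAsFactors = FALSE))
      }
    }
    if (tr$type == "nadph") {
      nadp_cmp <- if (is.null(tr$nadp_compound)) "NADP+" else tr$nadp_compound
      nadph_cmp <- if (is.null(tr$nadph_compound)) "NADPH" else tr$nadph_compound
      if (!nadp_cmp %in% names(res$mids) || !nadph_cmp %in% names(res$mids))
        stop("track ", sQuote(nm), ": compounds ", sQuote(nadp_cmp), " and ",
             sQuote(nadph_cmp), " are both required")
      ss <- intersect(names(res$mids[[nadp_cmp]]), names(res$mids[[nadph_cmp]]))
      if (!length(ss)) stop("track ", sQuote(nm), ": no paired samples")
      grp <- if (nrow(meta)) meta$group[match(ss, meta$sample)] else rep("all", length(ss))
      grp[is.na(grp)] <- "all"
      active_h <- active_h_cohort(res$mids[[nadp_cmp]][ss],
                                  res$mids[[nadph_cmp]][ss],
                                  group = grp, sample = ss)
    }
  }
  if (is.null(corrected)) stop("no compounds were corrected; check the peak tables")

  assays <- if (!is.null(cfg$assays)) process_assays(cfg) else NULL

  paths <- character(0)
  wout <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths[[name]] <<- p
  }
  wout(corrected, "corrected_mids.csv")
  wout(metrics, "labeling_metrics.csv")
  if (!is.null(normalized)) wout(normalized, "normalized_enrichment.csv")
  if (!is.null(active_h)) {
    wout(active_h$samples, "active_h.csv")
    wout(active_h$summary, "active_h_summary.csv")
  }
  if (!is.null(assays)) wout(assays, "assays.csv")

  log_lines <- c(
    paste0("tracemid version: ", as.character(utils::packageVersion("tracemid"))),
    paste0("seed: ", if (is.null(cfg$seed)) "none" else cfg$seed),
    paste0("mode: ", cfg$mode),
    paste0("config: ", if (is.null(cfg$.config_path)) "<list>"
           else basename(cfg$.config_path)),
    paste0("config md5: ", if (is.null(cfg$.config_path)) "NA"
           else unname(tools::md5sum(cfg$.config_path))),
    paste0("outputs: ", paste(names(paths), collapse = ", ")))
  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  paths[["run.log"]] <- log_path

  invisible(structure(list(output_dir = out_dir, paths = paths,
                           corrected = corrected, metrics = metrics,
                           normalized = normalized, active_h = active_h,
                           assays = assays, serum = serum),
                      class = "pipeline_run"))
}

# rbind-safe: ensure optional columns exist
merge_cols <- function(df) {
  if (!"essential" %in% names(df)) df$essential <- NA
  df
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d corrected MID(s), outputs in %s\n",
              if (is.null(x$corrected)) 0L else length(unique(
                paste(x$corrected$compound, x$corrected$sample))),
              x$output_dir))
  cat("  files:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}
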