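# Forward simulator: everything the tracing experiments measure, with known
# ground truth, so every pipeline stage is testable without LC-MS data.

nadp_formula <- function() "C21H28N7O17P3"
nadph_formula <- function() "C21H29N7O17P3"

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# multiplicative lognormal noise factors with mean 1 and coefficient of
# variation cv
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a true tracer-labeling MID
#'
#' Default model: each of `n_atoms` label-capable atoms carries tracer
#' independently with probability `enrichment`, giving a
#' `Binomial(n_atoms, enrichment)` isotopologue distribution. A `"custom"`
#' escape hatch accepts an arbitrary fraction vector.
#'
#' @param n_atoms Number of label-capable atoms.
#' @param enrichment Per-atom labeling probability in \[0, 1\].
#' @param model `"binomial"` (default) or `"custom"`.
#' @param custom Fraction vector used when `model = "custom"`.
#' @return A MID over shifts `0..n_atoms` (or the custom vector, validated).
#' @examples
#' simulate_true_mid(2, 0.5)  # c(0.25, 0.5, 0.25)
#' @export
simulate_true_mid <- function(n_atoms, enrichment, model = c("binomial", "custom"),
                              custom = NULL) {
  model <- match.arg(model)
  if (model == "custom") {
    if (is.null(custom)) stop("model = \"custom\" requires a custom MID")
    return(check_mid(custom))
  }
  if (!is.numeric(enrichment) || enrichment < 0 || enrichment > 1)
    stop("enrichment must lie in [0, 1]")
  stats::dbinom(0:n_atoms, n_atoms, enrichment)
}

#' Forward-simulate raw isotopologue intensities
#'
#' Applies the forward model inverse to [correct_intensities()]: raw
#' intensities are `scale * (M %*% true_mid)` under the compound's correction
#' matrix `M` (natural abundance + tracer impurity), with multiplicative
#' lognormal noise of coefficient of variation `noise_cv` applied to the
#' intensities — where measurement noise physically enters — not to
#' fractions. The per-sample `scale` is drawn log-uniformly over
#' `[1e5, 1e8]` to exercise scale invariance downstream.
#'
#' @param true_mid True labeling-state MID (length `n_label_atoms + 1`).
#' @param formula Metabolite formula.
#' @param tracer A [tracer_spec()] whose `n_label_atoms` matches `true_mid`.
#' @param noise_cv Multiplicative intensity noise CV (0 = noise-free).
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @param mode Correction-matrix resolution mode.
#' @param max_shift Largest simulated mass shift (default `n_label_atoms`).
#' @param scale Optional fixed intensity scale; drawn randomly when `NULL`.
#' @param isotopes Isotope abundance table.
#' @return Numeric vector of raw intensities over shifts `0..max_shift`.
#' @export
simulate_measurement <- function(true_mid, formula, tracer, noise_cv = 0,
                                 seed = NULL, mode = "high_res",
                                 max_shift = length(true_mid) - 1L, scale = NULL,
                                 isotopes = default_isotope_table()) {
  x <- check_mid(true_mid, what = "true MID")
  if (!inherits(tracer, "tracer_spec")) stop("tracer must be a tracer_spec")
  if (length(x) != tracer$n_label_atoms + 1L)
    stop("true_mid length must equal n_label_atoms + 1")
  cm <- build_correction_matrix(formula, tracer, max_shift, mode, isotopes)
  expected <- as.vector(cm$matrix %*% x)
  with_seed(seed, {
    if (is.null(scale)) scale <- 10^stats::runif(1, 5, 8)
    expected * scale * lnoise(length(expected), noise_cv)
  })
}

#' Forward-simulate a raw NADP+/NADPH isotopologue pair
#'
#' The true NADPH MID is the active-hydride mixture
#' `(1 - p) * c(nadp, 0) + p * c(0, nadp)`; both species are then pushed
#' through [simulate_measurement()] with an H tracer.
#'
#' @param nadp_true_mid True 2H MID of NADP+ (length >= 2).
#' @param p Active-hydride labeling fraction in \[0, 1\].
#' @param noise_cv,seed,purity,mode,isotopes Passed to the measurement model.
#' @return List with `nadp_raw`, `nadph_raw`, `nadp_true`, `nadph_true`, and
#'   the two correction matrices (`nadp_matrix`, `nadph_matrix`) used.
#' @examples
#' sim <- simulate_nadph_pair(c(0.8, 0.2), p = 0.3)
#' sim$nadph_true  # c(0.56, 0.38, 0.06)
#' @export
simulate_nadph_pair <- function(nadp_true_mid, p, noise_cv = 0, seed = NULL,
                                purity = 1, mode = "high_res",
                                isotopes = default_isotope_table()) {
  a <- check_mid(nadp_true_mid, what = "NADP+ true MID")
  if (length(a) < 2L) stop("NADP+ MID needs at least two entries (one labelable atom)")
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  nadph_true <- (1 - p) * c(a, 0) + p * c(0, a)
  tr_nadp <- tracer_spec("H", length(a) - 1L, purity)
  tr_nadph <- tracer_spec("H", length(a), purity)
  with_seed(seed, {
    nadp_raw <- simulate_measurement(a, nadp_formula(), tr_nadp, noise_cv,
                                     mode = mode, isotopes = isotopes)
    nadph_raw <- simulate_measurement(nadph_true, nadph_formula(), tr_nadph,
                                      noise_cv, mode = mode, isotopes = isotopes)
    list(nadp_raw = nadp_raw, nadph_raw = nadph_raw,
         nadp_true = a, nadph_true = nadph_true,
         nadp_matrix = build_correction_matrix(nadp_formula(), tr_nadp,
                                               length(a) - 1L, mode, isotopes),
         nadph_matrix = build_correction_matrix(nadph_formula(), tr_nadph,
                                                length(a), mode, isotopes))
  })
}

#' Group specification for the cohort simulator
#'
#' Ground-truth parameters of one genotype group.
#'
#' @param p_active_h True NADPH active-hydride labeling fraction.
#' @param serum_enrichment Serum \[U-13C6\]-glucose M+6 fraction (the serum
#'   glucose MID is simulated as a two-point M+0/M+6 mixture, so the M+6
#'   fraction and the atom-fraction enrichment coincide).
#' @param serine_enrichment Per-carbon glucose-derived 13C enrichment of
#'   tumor serine (and glycine).
#' @param fa_new_fraction Newly-synthesized fraction of C16:0 during D2O
#'   exposure (C18:2, essential, is fixed at 0).
#' @param h_incorporation Per-hydrogen deuterium incorporation probability in
#'   newly made fatty acid (~ body-water D2O enrichment).
#' @param nadp_enrichment Background per-site 2H enrichment of NADP+.
#' @return A list of class `sim_group`.
#' @export
sim_group <- function(p_active_h, serum_enrichment, serine_enrichment,
                      fa_new_fraction, h_incorporation, nadp_enrichment = 0.02) {
  vals <- c(p_active_h = p_active_h, serum_enrichment = serum_enrichment,
            serine_enrichment = serine_enrichment,
            fa_new_fraction = fa_new_fraction,
            h_incorporation = h_incorporation, nadp_enrichment = nadp_enrichment)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all group fractions must lie in [0, 1]")
  if (serum_enrichment <= 0)
    stop("serum_enrichment must be strictly positive")
  structure(as.list(vals), class = "sim_group")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions of a WT-vs-G6PD-KO lung-tumor
#' cohort: the knockout group has higher NADPH active-hydride labeling from
#' serine, lower glucose-derived serine labeling, and lower de novo
#' lipogenesis; serum tracer exposure is shared. See the methods vignette for
#' how each default was chosen.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_per_group Mice per group.
#' @param groups Named list of [sim_group()] specifications.
#' @param noise_cv Multiplicative CV of intensity noise.
#' @param purity Per-atom tracer isotopic purity.
#' @param mode Correction-matrix resolution mode.
#' @param bio_cv Between-mouse (multiplicative) biological CV applied to the
#'   group ground-truth fractions; 0 disables biological spread.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_per_group = 8L,
                       groups = list(
                         WT = sim_group(0.05, 0.35, 0.15, 0.30, 0.045),
                         KO = sim_group(0.15, 0.35, 0.08, 0.10, 0.045)),
                       noise_cv = 0.02, purity = 0.99,
                       mode = c("high_res", "nominal"), bio_cv = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("seed must be an integer")
  if (!is.numeric(n_per_group) || n_per_group < 1 || n_per_group != round(n_per_group))
    stop("n_per_group must be a positive integer")
  if (!length(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a non-empty named list")
  for (g in groups) if (!inherits(g, "sim_group")) stop("each group must be a sim_group")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (bio_cv < 0) stop("bio_cv must be non-negative")
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 groups = groups, noise_cv = noise_cv, purity = purity,
                 mode = mode, bio_cv = bio_cv),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, %d per group, noise_cv %.3g, purity %.3g, %s mode\n",
              x$seed, x$n_per_group, x$noise_cv, x$purity, x$mode))
  for (g in names(x$groups)) {
    gg <- x$groups[[g]]
    cat(sprintf("  %s: p = %.3g, serum = %.3g, serine = %.3g, FA new = %.3g, q(2H) = %.3g\n",
                g, gg$p_active_h, gg$serum_enrichment, gg$serine_enrichment,
                gg$fa_new_fraction, gg$h_incorporation))
  }
  invisible(x)
}

label_tag <- function(element, shift) {
  ifelse(shift == 0L, "C12 PARENT",
         paste0(ifelse(element == "C", "C13", "D"), "-label-", shift))
}

# one peak table (compound x shift rows, one intensity column per sample)
sim_peak_table <- function(defs, truth, config) {
  cols <- list()
  meta <- NULL
  for (d in defs) {
    shifts <- 0:d$n_label
    meta <- rbind(meta, data.frame(
      compound = d$compound, formula = d$formula,
      isotopeLabel = label_tag(d$element, shifts), stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(truth))) {
    col <- numeric(0)
    for (d in defs) {
      raw <- simulate_measurement(
        d$mid(truth[i, ]), d$formula,
        tracer_spec(d$element, d$n_label, config$purity),
        noise_cv = config$noise_cv, mode = config$mode)
      col <- c(col, raw)
    }
    cols[[truth$sample[i]]] <- col
  }
  cbind(meta, as.data.frame(cols, check.names = FALSE))
}

jitter_frac <- function(x, cv) {
  if (cv <= 0 || x == 0) return(x)
  min(x * exp(stats::rnorm(1, 0, cv)), 1)
}

#' Simulate a full tracer cohort with ground truth
#'
#' Forward-simulates every data product the pipeline consumes, for a WT/KO
#' cohort with known ground truth: raw peak tables for the three tracer
#' tracks (13C-glucose water-soluble metabolites and serum glucose,
#' 2H-serine NADP+/NADPH pairs, D2O saponified fatty acids), bench-assay
#' tables (serine consumption, ROS, confluence time courses, redox pools,
#' H2O2 dose response), and a per-sample ground-truth table. Identical
#' configurations (including seed) give byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: `config`, `samples` (metadata),
#'   `peak_tables` (named list of data frames), `assays` (named list),
#'   `truth` (per-sample ground truth).
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 42, n_per_group = 2))
#' coh$truth[, c("sample", "p_active_h", "serine_enrichment")]
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  groups <- names(config$groups)
  samples <- data.frame(
    sample = unlist(lapply(groups, function(g) paste0(g, "_", seq_len(config$n_per_group)))),
    group = rep(groups, each = config$n_per_group),
    stringsAsFactors = FALSE)
  samples$mouse_id <- samples$sample

  truth <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    g <- config$groups[[samples$group[i]]]
    data.frame(
      sample = samples$sample[i], group = samples$group[i],
      p_active_h = jitter_frac(g$p_active_h, config$bio_cv),
      serum_enrichment = jitter_frac(g$serum_enrichment, config$bio_cv),
      serine_enrichment = jitter_frac(g$serine_enrichment, config$bio_cv),
      fa_new_fraction = jitter_frac(g$fa_new_fraction, config$bio_cv),
      h_incorporation = g$h_incorporation,
      nadp_enrichment = jitter_frac(g$nadp_enrichment, config$bio_cv),
      stringsAsFactors = FALSE)
  }))
  truth$serine_labeled_fraction <- 1 - (1 - truth$serine_enrichment)^3
  n_h_c16 <- fatty_acid_formula("C16:0")[["H"]]
  truth$c16_labeled_fraction <-
    truth$fa_new_fraction * (1 - (1 - truth$h_incorporation)^n_h_c16)

  peak_tables <- list(
    serine13C = sim_peak_table(list(
      list(compound = "serine", formula = "C3H7NO3", element = "C", n_label = 3L,
           mid = function(tr) simulate_true_mid(3L, tr$serine_enrichment)),
      list(compound = "glycine", formula = "C2H5NO2", element = "C", n_label = 2L,
           mid = function(tr) simulate_true_mid(2L, tr$serine_enrichment))),
      truth, config),
    serum_glucose13C = sim_peak_table(list(
      list(compound = "glucose", formula = "C6H12O6", element = "C", n_label = 6L,
           mid = function(tr) {
             m <- numeric(7); m[1] <- 1 - tr$serum_enrichment
             m[7] <- tr$serum_enrichment; m
           })),
      truth, config),
    nadph2H = sim_peak_table(list(
      list(compound = "NADP+", formula = nadp_formula(), element = "H", n_label = 2L,
           mid = function(tr) simulate_true_mid(2L, tr$nadp_enrichment)),
      list(compound = "NADPH", formula = nadph_formula(), element = "H", n_label = 3L,
           mid = function(tr) {
             a <- simulate_true_mid(2L, tr$nadp_enrichment)
             (1 - tr$p_active_h) * c(a, 0) + tr$p_active_h * c(0, a)
           })),
      truth, config),
    fattyacids2H = sim_peak_table(list(
      list(compound = "C16:0", formula = format(fatty_acid_formula("C16:0")),
           element = "H", n_label = n_h_c16,
           mid = function(tr) {
             syn <- simulate_true_mid(n_h_c16, tr$h_incorporation)
             (1 - tr$fa_new_fraction) * c(1, numeric(n_h_c16)) + tr$fa_new_fraction * syn
           }),
      list(compound = "C18:2", formula = format(fatty_acid_formula("C18:2")),
           element = "H", n_label = fatty_acid_formula("C18:2")[["H"]],
           mid = function(tr) c(1, numeric(fatty_acid_formula("C18:2")[["H"]])))),
      truth, config))

  assays <- sim_assays(groups, config)

  structure(list(config = config, samples = samples,
                 peak_tables = peak_tables, assays = assays, truth = truth),
            class = "sim_cohort")
}

# bench-assay tables; magnitudes are realistic defaults, group effect
# directions follow the tracing findings (KO: higher serine uptake, higher
# ROS, slower growth, impaired redox ratios)
sim_assays <- function(groups, config) {
  par <- list(
    WT = list(cells0 = 0.5e5, growth = 0.035, consumption = 12, ros = 3000,
              slope = 0.75, nadph = 12, nadp = 10, gsh = 800, gssg = 100,
              base_count = 2e5, h2o2_rel = c(1, 0.9, 0.75, 0.5)),
    KO = list(cells0 = 1e5, growth = 0.02, consumption = 25, ros = 6000,
              slope = 0.45, nadph = 6, nadp = 10, gsh = 400, gssg = 100,
              base_count = 1.2e5, h2o2_rel = c(1, 0.7, 0.45, 0.2)))
  # unknown group names reuse WT magnitudes
  pick <- function(g) if (g %in% names(par)) par[[g]] else par$WT

  cons <- NULL; ros <- NULL; prol <- NULL; redox <- NULL; h2o2 <- NULL
  for (g in groups) {
    p <- pick(g)
    for (t in c(0, 24, 36, 48, 60)) for (w in 1:2) {
      c0 <- p$cells0 * lnoise(1, 0.05)
      ct <- c0 * exp(p$growth * t) * lnoise(1, 0.03)
      ser <- max(60 - p$consumption * (ct - c0) / 1e6 + stats::rnorm(1, 0, 0.2), 0)
      cons <- rbind(cons, data.frame(
        group = g, well = sprintf("%s_t%d_w%d", g, t, w), timepoint_h = t,
        serine_ug = ser, cells = ct, stringsAsFactors = FALSE))
    }
    for (w in 1:3) {
      cells <- 0.9 * lnoise(1, 0.1)
      f0 <- 500 * lnoise(1, 0.05)
      ros <- rbind(ros, data.frame(
        group = g, well = sprintf("%s_w%d", g, w),
        f_stained = f0 + p$ros * cells * lnoise(1, 0.05), f_unstained = f0,
        cells_millions = cells, stringsAsFactors = FALSE))
    }
    for (w in 1:3) {
      tt <- seq(0, 96, by = 2)
      conf <- pmin(pmax(5 + p$slope * tt + stats::rnorm(length(tt), 0, 0.5), 0), 100)
      prol <- rbind(prol, data.frame(
        group = g, well = sprintf("%s_w%d", g, w), time_h = tt,
        confluence_pct = conf, stringsAsFactors = FALSE))
    }
    for (w in 1:4) redox <- rbind(redox, data.frame(
      group = g, replicate = w,
      nadph = p$nadph * lnoise(1, 0.1), nadp = p$nadp * lnoise(1, 0.1),
      gsh = p$gsh * lnoise(1, 0.1), gssg = p$gssg * lnoise(1, 0.1),
      stringsAsFactors = FALSE))
    doses <- c(0, 20, 40, 80)
    for (di in seq_along(doses)) for (w in 1:3) h2o2 <- rbind(h2o2, data.frame(
      group = g, dose_umol_l = doses[di], well = w,
      count = p$base_count * p$h2o2_rel[di] * lnoise(1, 0.05),
      stringsAsFactors = FALSE))
  }
  list(serine_consumption = cons, ros = ros, proliferation = prol,
       redox = redox, h2o2 = h2o2)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d sample(s) in %d group(s); peak tables: %s\n",
              nrow(x$samples), length(unique(x$samples$group)),
              paste(names(x$peak_tables), collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the peak tables, sample metadata, assay tables, ground truth, a
#' config echo, and a ready-to-run pipeline configuration into `dir`, in the
#' same CSV dialect [read_peak_table()] consumes. Output is byte-identical
#' for identical cohorts.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the written pipeline config.
#' @export
write_sim_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "sim_cohort")) stop("cohort must be a sim_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = TRUE)
  for (nm in names(cohort$peak_tables))
    wcsv(cohort$peak_tables[[nm]], paste0("peaks_", nm, ".csv"))
  wcsv(cohort$samples, "samples.csv")
  wcsv(cohort$truth, "truth.csv")
  for (nm in names(cohort$assays))
    wcsv(cohort$assays[[nm]], paste0("assay_", nm, ".csv"))
  cfg <- cohort$config
  yaml::write_yaml(list(seed = cfg$seed, n_per_group = cfg$n_per_group,
                        noise_cv = cfg$noise_cv, purity = cfg$purity,
                        mode = cfg$mode, bio_cv = cfg$bio_cv,
                        groups = lapply(cfg$groups, unclass)),
                   file.path(dir, "sim_config.yaml"))
  pipeline <- list(
    seed = cfg$seed,
    mode = cfg$mode,
    output_dir = "results",
    samples = "samples.csv",
    serum = list(peaks = "peaks_serum_glucose13C.csv", compound = "glucose",
                 denominator = "fractional_enrichment",
                 tracer = list(element = "C", purity = cfg$purity)),
    tracks = list(
      serine13C = list(peaks = "peaks_serine13C.csv", type = "watersoluble",
                       normalize_to_serum = TRUE,
                       tracer = list(element = "C", purity = cfg$purity)),
      nadph2H = list(peaks = "peaks_nadph2H.csv", type = "nadph",
                     nadp_compound = "NADP+", nadph_compound = "NADPH",
                     tracer = list(element = "H", purity = cfg$purity)),
      fattyacids2H = list(peaks = "peaks_fattyacids2H.csv", type = "fatty_acid",
                          essential = list("C18:2"),
                          tracer = list(element = "H", purity = cfg$purity))),
    assays = list(serine_consumption = "assay_serine_consumption.csv",
                  ros = "assay_ros.csv", proliferation = "assay_proliferation.csv",
                  redox = "assay_redox.csv", h2o2 = "assay_h2o2.csv"))
  cfg_path <- file.path(dir, "pipeline_config.yaml")
  yaml::write_yaml(pipeline, cfg_path)
  invisible(cfg_path)
}
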