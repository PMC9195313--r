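## End-to-end orchestration: simulate -> ingest/preprocess -> ERP ->
## time-frequency -> cluster permutation -> coupling -> mixed models, with
## per-stage derived seeds so toggling one stage never shifts another's
## random draws, and a JSON manifest of counts and parameters.

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates (or reuses) a synthetic study on disk, then runs every
#' analysis stage, writing TSV/JSON outputs under `out_dir`. Re-running
#' with an identical configuration and seed reproduces all stochastic
#' stages exactly.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param n_perm cluster permutations
#' @param n_surrogates PAC/PSI surrogates
#' @param voxel_p voxel-level threshold for the cluster test
#' @param tf_decim time-axis decimation for stored time-frequency maps
#' @param stages character subset of
#'   c("simulate", "erp", "gamma", "cluster", "coupling", "stats")
#' @param seed master seed (defaults to the config seed)
#' @return manifest list, invisibly; also written as manifest.json
#' @export
run_pipeline <- function(config, out_dir, n_perm = 3000, n_surrogates = 200,
                         voxel_p = 0.05, tf_decim = 8L,
                         stages = c("simulate", "erp", "gamma", "cluster",
                                    "coupling", "stats"),
                         seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = stages,
                   parameters = list(
                     fs = config$fs, n_per_category = config$n_per_category,
                     n_patients_per_group = config$n_patients_per_group,
                     bandpass_hz = c(0.5, 20), sd_reject_factor = 2.5,
                     n_freqs = 40, freq_range_hz = c(1, 200),
                     db_baseline_ms = 1100, gamma_band_hz = c(45, 150),
                     n_perm = n_perm, voxel_p = voxel_p,
                     n_surrogates = n_surrogates),
                   counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  raw_dir <- file.path(out_dir, "raw")
  if ("simulate" %in% stages) {
    study <- stage("simulate", {
      cfg <- config; cfg$seed <- derive_seed(seed, "simulate")
      generate_study(cfg, raw_dir)
    })
  } else {
    study <- read.delim(file.path(raw_dir, "study.tsv"))
    attr(study, "channels_tsv") <- file.path(raw_dir, "channels.tsv")
  }
  write.table(study, file.path(raw_dir, "study.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ch_tsv <- attr(study, "channels_tsv")

  load_patient <- function(i) {
    rr <- read_recording(study$edf[i], ch_tsv, study$events[i])
    rr$recording <- resample_to_1024(rr$recording)
    rr
  }

  erp_rows <- NULL
  if ("erp" %in% stages) {
    erp_rows <- stage("erp", {
      rows <- lapply(seq_len(nrow(study)), function(i) {
        rr <- load_patient(i)
        ep <- epoch_recording(rereference(rr$recording, "fz_monopolar"),
                              rr$events)
        ep <- reject_outlier_epochs(ep)
        ep <- bandpass_erp(ep)
        trial_peak_amplitudes(ep)
      })
      do.call(rbind, rows)
    })
    write.table(erp_rows, file.path(out_dir, "erp_trials.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$counts$erp_rows <- nrow(erp_rows)
  }

  gamma_rows <- NULL; region_maps <- NULL
  if (any(c("gamma", "cluster", "coupling") %in% stages)) {
    res <- stage("gamma", {
      rows <- list(); maps <- list(); eps <- list()
      for (i in seq_len(nrow(study))) {
        rr <- load_patient(i)
        ep <- epoch_recording(rereference(rr$recording, "bipolar"),
                              rr$events)
        ep <- reject_outlier_epochs(ep)
        eps[[study$patient[i]]] <- ep
        tf <- morlet_power(subtract_erp(ep), decim = tf_decim)
        tf <- baseline_db(tf)
        rows[[i]] <- window_gamma_power(tf)
        for (region in unique(ep$channels$region)) {
          chs <- which(ep$channels$region == region)
          mm <- lapply(chs, function(ch) subject_map(tf, ch)$map)
          maps[[paste(study$patient[i], region, sep = ".")]] <-
            list(map = Reduce(`+`, mm) / length(mm), region = region,
                 patient = study$patient[i], group = study$group[i],
                 freqs = tf$freqs, t = tf$t)
        }
      }
      list(rows = do.call(rbind, rows), maps = maps, eps = eps)
    })
    gamma_rows <- res$rows
    region_maps <- res$maps
    write.table(gamma_rows, file.path(out_dir, "gamma_trials.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$gamma_rows <- nrow(gamma_rows)
    manifest$counts$trials_rejected <- vapply(res$eps, function(e)
      sum(!e$kept_mask), integer(1))
  }

  if ("cluster" %in% stages) {
    cl_tables <- stage("cluster", {
      out <- list()
      for (region in unique(vapply(region_maps, `[[`, "", "region"))) {
        sel <- Filter(function(m) m$region == region, region_maps)
        grp <- vapply(sel, `[[`, "", "group")
        if (sum(grp == "O") < 2 || sum(grp == "M") < 2) next
        cres <- cluster_permutation(
          lapply(sel[grp == "O"], `[[`, "map"),
          lapply(sel[grp == "M"], `[[`, "map"),
          n_perm = n_perm, voxel_p = voxel_p,
          seed = derive_seed(seed, paste0("cluster_", region)))
        tab <- cres$clusters
        tab$region <- region
        out[[region]] <- tab
        jsonlite::write_json(
          list(region = region, thr_hi = cres$thr_hi, thr_lo = cres$thr_lo,
               voxel_threshold = cres$voxel_threshold, n_perm = n_perm,
               seed = cres$seed),
          file.path(out_dir, paste0("cluster_", region, "_thresholds.json")),
          auto_unbox = TRUE, digits = NA)
      }
      out
    })
    cl_all <- do.call(rbind, cl_tables)
    write.table(cl_all, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$counts$surviving_clusters <-
      if (is.null(cl_all)) 0L else sum(cl_all$survives)
  }

  if ("coupling" %in% stages) {
    pair_tab <- stage("coupling", {
      specs <- config$coupling_specs
      out <- list()
      for (i in seq_len(nrow(study))) {
        ep <- res$eps[[study$patient[i]]]
        for (r in seq_len(nrow(specs))) {
          if (!specs$phase_region[r] %in% ep$channels$region ||
              !specs$amp_region[r] %in% ep$channels$region) next
          pch <- select_channel(ep, specs$phase_region[r])
          ach <- select_channel(ep, specs$amp_region[r])
          sd_seed <- derive_seed(seed, paste0("pac_", study$patient[i], r))
          pac_f <- pac_comodulogram(ep, pch, ach, FACE_CATEGORIES,
                                    n_surrogates = n_surrogates,
                                    seed = sd_seed)
          pac_m <- pac_comodulogram(ep, pch, ach, "mosaic",
                                    n_surrogates = n_surrogates,
                                    seed = sd_seed + 1L)
          psi <- psi_directionality(ep, pch, ach, FACE_CATEGORIES,
                                    n_surrogates = n_surrogates,
                                    seed = sd_seed + 2L)
          psi <- restrict_psi_to_pac(psi, pac_f)
          out[[length(out) + 1]] <- data.frame(
            patient = study$patient[i], group = study$group[i],
            phase_region = specs$phase_region[r],
            amp_region = specs$amp_region[r],
            pac_sig_faces = sum(pac_f$z >= 2),
            pac_sig_mosaics = sum(pac_m$z >= 2),
            psi_sig_pos = sum(psi$z >= 2, na.rm = TRUE),
            psi_sig_neg = sum(psi$z <= -2, na.rm = TRUE))
        }
      }
      do.call(rbind, out)
    })
    write.table(pair_tab, file.path(out_dir, "coupling_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ## a pair counts as coupled when its significant-pixel fraction clearly
    ## exceeds the surrogate chance level (~2.3% of the grid at z >= 2)
    npx <- length(pac_phase_freqs()) * length(pac_amp_freqs())
    manifest$counts$coupled_pairs_faces <-
      sum(pair_tab$pac_sig_faces / npx > 0.05)
    manifest$counts$coupled_pairs_mosaics <-
      sum(pair_tab$pac_sig_mosaics / npx > 0.05)
  }

  if ("stats" %in% stages) {
    fits <- stage("stats", {
      out <- list()
      for (region in REGIONS) {
        for (dep in c("erp", "gamma")) {
          rows <- if (dep == "erp") erp_rows else gamma_rows
          if (is.null(rows)) next
          rows <- rows[rows$region == region, , drop = FALSE]
          if (!nrow(rows)) next
          for (model in 1:2) {
            tab <- build_trial_table(rows, model = model)
            ft <- tryCatch(
              suppressMessages(fit_lme(tab, with_peaks = dep == "erp")),
              error = function(e) NULL)
            if (is.null(ft)) next
            tt <- ft$terms
            tt$region <- region; tt$dependent <- dep; tt$model <- model
            out[[length(out) + 1]] <- tt
          }
        }
      }
      do.call(rbind, out)
    })
    if (is.null(fits))
      fits <- data.frame(term = character(), F = numeric(),
                         df1 = numeric(), df2 = numeric(),
                         p_raw = numeric(), p_holm = numeric(),
                         region = character(), dependent = character(),
                         model = integer())
    write.table(fits, file.path(out_dir, "lme_terms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$counts$lme_fits <- length(unique(paste(fits$region,
                                                    fits$dependent,
                                                    fits$model)))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
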