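#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline with its
#' canonical default, plus the cohort source: either a simulation config
#' (the default synthetic cohort) or a directory holding an existing file
#' bundle in the package's formats. The config round-trips to YAML via
#' [write_config()] / [read_config()] and every value is recorded in the
#' run manifest.
#'
#' @param outdir output directory for the run.
#' @param seed integer seed governing all randomness in the run.
#' @param simulate generate the cohort (`TRUE`) or read it from
#'   `cohort_dir`.
#' @param cohort simulation config (see [default_cohort_config()]).
#' @param cohort_dir directory with an existing cohort bundle.
#' @param elocus_threshold eloci cutoff on the delta-S scale.
#' @param min_reads_cpg per-CpG coverage filter for single-CpG analyses.
#' @param min_window_reads per-window read threshold for epiallele loci.
#' @param dmr DMR-calling parameters, see [dmr_params()].
#' @param tree_min_reads,tree_min_mad coverage / MAD (percent) filters for
#'   phylogenetic tree features (promoter CpGs).
#' @param corr_min_reads,corr_min_mad filters for the distance-correlation
#'   feature space (all CpGs).
#' @param tau_delta_s,tau_epipoly quantile levels for the group
#'   comparisons of delta-S (1st percentile) and epipolymorphism (median).
#' @param epipoly_convention `"diversity"` or `"as_printed"`.
#' @param tile_size tile width for tile-level aggregation (bp).
#' @param cluster_min_reads coverage filter for the clustering feature set.
#' @param line1_min_reads coverage filter for LINE-1 CpGs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("methevo_run_"), seed = 1L,
                            simulate = TRUE,
                            cohort = default_cohort_config(),
                            cohort_dir = NULL,
                            elocus_threshold = -60,
                            min_reads_cpg = 10L, min_window_reads = 60L,
                            dmr = dmr_params(),
                            tree_min_reads = 50L, tree_min_mad = 10,
                            corr_min_reads = 20L, corr_min_mad = 20,
                            tau_delta_s = 0.01, tau_epipoly = 0.5,
                            epipoly_convention = "diversity",
                            tile_size = 5000L, cluster_min_reads = 50L,
                            line1_min_reads = 10L) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              cohort = cohort, cohort_dir = cohort_dir,
              elocus_threshold = elocus_threshold,
              min_reads_cpg = as.integer(min_reads_cpg),
              min_window_reads = as.integer(min_window_reads),
              dmr = unclass(dmr),
              tree_min_reads = as.integer(tree_min_reads),
              tree_min_mad = tree_min_mad,
              corr_min_reads = as.integer(corr_min_reads),
              corr_min_mad = corr_min_mad,
              tau_delta_s = tau_delta_s, tau_epipoly = tau_epipoly,
              epipoly_convention = epipoly_convention,
              tile_size = as.integer(tile_size),
              cluster_min_reads = as.integer(cluster_min_reads),
              line1_min_reads = as.integer(line1_min_reads))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "dmr")])
  if (!is.null(raw$dmr)) cfg$dmr <- do.call(dmr_params, raw$dmr)
  cfg$dmr <- unclass(cfg$dmr)
  cfg
}

#' Validate a pipeline config without running anything
#'
#' Checks threshold ranges and, for file-based cohorts, the existence and
#' basic format of the expected inputs. Never mutates state.
#'
#' @param config a [pipeline_config()].
#' @return Character vector of diagnostics (empty when the config is
#'   valid).
#' @export
validate_config <- function(config) {
  diag <- character(0)
  chk <- function(cond, msg) if (!cond) diag <<- c(diag, msg)
  chk(config$elocus_threshold < 0 && config$elocus_threshold > -100,
      "elocus_threshold must be in (-100, 0)")
  for (tau in c(config$tau_delta_s, config$tau_epipoly)) {
    chk(tau > 0 && tau < 1, sprintf("quantile level %g outside (0, 1)", tau))
  }
  chk(config$min_reads_cpg >= 1, "min_reads_cpg must be >= 1")
  chk(config$min_window_reads >= 1, "min_window_reads must be >= 1")
  chk(config$epipoly_convention %in% c("diversity", "as_printed"),
      "epipoly_convention must be 'diversity' or 'as_printed'")
  d <- config$dmr
  chk(d$min_abs_delta_beta > 0 && d$min_abs_delta_beta < 1,
      "dmr min_abs_delta_beta must be in (0, 1)")
  chk(d$max_p > 0 && d$max_p <= 1, "dmr max_p must be in (0, 1]")
  if (!isTRUE(config$simulate)) {
    if (is.null(config$cohort_dir) || !dir.exists(config$cohort_dir)) {
      diag <- c(diag, sprintf("cohort_dir '%s' does not exist",
                              config$cohort_dir %||% "<unset>"))
    } else {
      for (f in c("samples.csv", "mutations.tsv")) {
        p <- file.path(config$cohort_dir, f)
        chk(file.exists(p), sprintf("missing input file '%s'", p))
      }
      beds <- list.files(file.path(config$cohort_dir, "regions"),
                         pattern = "\\.bed$", full.names = TRUE)
      for (b in beds) {
        df <- try(utils::read.table(b, sep = "\t"), silent = TRUE)
        if (!inherits(df, "try-error") && ncol(df) >= 3L &&
            any(df[[2L]] >= df[[3L]])) {
          diag <- c(diag, sprintf("BED '%s' has start >= end", b))
        }
      }
    }
  }
  diag
}

#' Load a cohort file bundle
#'
#' Reads the bundle written by [simulate_cohort()] (or assembled by hand in
#' the same layout): `samples.csv`, `coverage/<sample>.cov`,
#' `patterns/<sample>.tsv`, `regions/*.bed`, `mutations.tsv`.
#'
#' @param dir bundle directory.
#' @param min_window_reads window read threshold passed to
#'   [read_patterns()].
#' @return List: `samples`, `profiles`, `epialleles`, `regions`,
#'   `mutations`.
#' @export
load_cohort <- function(dir, min_window_reads = 60L) {
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  profiles <- list(); epialleles <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    cov <- file.path(dir, "coverage", paste0(sid, ".cov"))
    if (!file.exists(cov)) stop("missing coverage file '", cov, "'")
    profiles[[sid]] <- read_coverage(
      cov, min_reads = 1L, sample_id = sid,
      patient_id = samples$patient_id[i], lesion_id = samples$lesion_id[i],
      stage = as.character(samples$stage[i]), role = samples$role[i])
    pat <- file.path(dir, "patterns", paste0(sid, ".tsv"))
    if (file.exists(pat)) {
      epialleles[[sid]] <- read_patterns(pat, min_total_reads =
                                           min_window_reads)
    }
  }
  beds <- list.files(file.path(dir, "regions"), pattern = "\\.bed$",
                     full.names = TRUE)
  regions <- stats::setNames(lapply(beds, read_bed),
                             sub("\\.bed$", "", basename(beds)))
  mutations <- if (file.exists(file.path(dir, "mutations.tsv")))
    read_mutations(file.path(dir, "mutations.tsv")) else list()
  list(samples = samples, profiles = profiles, epialleles = epialleles,
       regions = regions, mutations = mutations)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## prepend constant id columns to a data.frame without row-name noise
add_cols <- function(df, ...) {
  extra <- list(...)
  rownames(df) <- NULL
  out <- cbind(as.data.frame(lapply(extra, rep_len, nrow(df)),
                             stringsAsFactors = FALSE), df)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: cohort simulation (or loading),
#' epiallele ITH metrics, DMR calling and classification, phylogenetics,
#' genomic context, and a report with profile correlations, tile-level PCA
#' and hierarchical clustering. Each stage writes TSV/Newick/JSON outputs
#' under its own subdirectory of `config$outdir`; a `manifest.json` records
#' every parameter and the MD5 of every tabular output, so reruns with the
#' same config and seed are byte-reproducible (figures exempt). A stage
#' failure raises an error naming the stage; outputs of completed stages
#' are preserved.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate", "ith", "dmr", "phylo", "context", "report")`.
#' @return Invisibly, a list with `outdir`, `manifest` and the loaded
#'   `cohort`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "ith", "dmr", "phylo",
                                    "context", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  diag <- validate_config(config)
  if (length(diag)) stop("invalid config:\n  ", paste(diag, collapse = "\n  "))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  done <- character(0)
  cohort_dir <- config$cohort_dir
  if ("simulate" %in% stages && isTRUE(config$simulate)) {
    cohort_dir <- file.path(outdir, "cohort")
    run_stage("simulate",
              simulate_cohort(config$cohort, seed = config$seed,
                              outdir = cohort_dir))
    done <- c(done, "simulate")
  }
  if (is.null(cohort_dir)) stop("no cohort available: set cohort_dir or simulate")
  cohort <- run_stage("load",
                      load_cohort(cohort_dir, config$min_window_reads))
  samples <- cohort$samples
  tumors <- samples$sample_id[samples$role == "tumor"]
  normal_of <- function(sid) {
    pid <- samples$patient_id[samples$sample_id == sid]
    samples$sample_id[samples$patient_id == pid & samples$role == "normal"][1L]
  }
  stage_map <- stats::setNames(as.character(samples$stage),
                               samples$sample_id)
  stage_of <- function(sid) unname(stage_map[sid])
  lesion_map <- stats::setNames(samples$lesion_id, samples$sample_id)
  lesion_of <- function(sid) unname(lesion_map[sid])
  strat_sets <- cohort$regions[intersect(
    c("promoter", "enhancer", "transcribed", "heterochromatin", "repeat",
      "PMD"), names(cohort$regions))]
  all_records <- NULL

  if ("ith" %in% stages) {
    run_stage("ith", {
      d <- file.path(outdir, "ith"); dir.create(d, showWarnings = FALSE)
      recs <- list()
      for (sid in tumors) {
        nid <- normal_of(sid)
        if (is.null(cohort$epialleles[[sid]]) ||
            is.null(cohort$epialleles[[nid]])) next
        recs[[sid]] <- entropy_shift(cohort$epialleles[[sid]],
                                     cohort$epialleles[[nid]],
                                     config$elocus_threshold)
      }
      all_records <- recs
      write_tsv(do.call(rbind, lapply(names(recs), function(sid) {
        add_cols(recs[[sid]], sample_id = sid, stage = stage_of(sid))
      })), file.path(d, "shift_records.tsv"))
      el <- summarize_eloci(recs)
      el$stage <- stage_of(el$sample_id)
      write_tsv(el, file.path(d, "eloci_summary.tsv"))
      pooled <- do.call(rbind, lapply(names(recs), function(sid) {
        data.frame(stage = stage_of(sid), delta_S = recs[[sid]]$delta_S,
                   epipoly = recs[[sid]]$epipoly_sample,
                   stringsAsFactors = FALSE)
      }))
      q1 <- group_quantile(pooled$delta_S, pooled$stage, config$tau_delta_s)
      q1$metric <- "delta_S"
      q2 <- group_quantile(pooled$epipoly, pooled$stage, config$tau_epipoly)
      q2$metric <- "epipolymorphism"
      write_tsv(rbind(q1, q2), file.path(d, "stage_quantiles.tsv"))
      strat <- lapply(names(recs), function(sid) {
        st <- stratify_shift_records(recs[[sid]], strat_sets,
                                     partitions = intersect(
                                       c("PMD", "repeat"), names(strat_sets)))
        do.call(rbind, lapply(names(st), function(nm) {
          if (nrow(st[[nm]]) == 0L) return(NULL)
          data.frame(sample_id = sid, stage = stage_of(sid), stratum = nm,
                     delta_S = st[[nm]]$delta_S, stringsAsFactors = FALSE)
        }))
      })
      strat <- do.call(rbind, strat)
      sq <- do.call(rbind, lapply(split(strat, strat$stratum), function(g) {
        q <- group_quantile(g$delta_S, g$stage, config$tau_delta_s)
        add_cols(q, stratum = g$stratum[1L])
      }))
      write_tsv(sq, file.path(d, "stratum_quantiles.tsv"))
    })
    done <- c(done, "ith")
  }

  dmr_tables <- list()
  if ("dmr" %in% stages) {
    run_stage("dmr", {
      d <- file.path(outdir, "dmr"); dir.create(d, showWarnings = FALSE)
      params <- do.call(dmr_params, config$dmr)
      cls_counts <- list(); strata <- list(); tiles <- list()
      for (sid in tumors) {
        nid <- normal_of(sid)
        dm <- call_dmrs(cohort$profiles[[sid]], cohort$profiles[[nid]],
                        params)
        dmr_tables[[sid]] <- dm
        cl <- classify_cpg_sites(cohort$profiles[[sid]],
                                 cohort$profiles[[nid]], dm,
                                 min_reads = config$min_reads_cpg)
        cls_counts[[sid]] <- data.frame(
          sample_id = sid, stage = stage_of(sid),
          n_assessed = nrow(cl),
          n_hyper = sum(cl$label == "hyper"),
          n_hypo = sum(cl$label == "hypo"), stringsAsFactors = FALSE)
        st <- stratify_dmrs(dm, strat_sets,
                            partitions = intersect(c("PMD", "repeat"),
                                                   names(strat_sets)))
        strata[[sid]] <- add_cols(st, sample_id = sid, stage = stage_of(sid))
      }
      dmr_all <- do.call(rbind, lapply(names(dmr_tables), function(sid) {
        dm <- dmr_tables[[sid]]
        if (nrow(dm) == 0L) return(NULL)
        add_cols(dm, sample_id = sid, stage = stage_of(sid))
      }))
      if (is.null(dmr_all)) {
        dmr_all <- data.frame(sample_id = character(0))
      }
      write_tsv(dmr_all, file.path(d, "dmrs.tsv"))
      cc <- do.call(rbind, cls_counts)
      cc$norm_hyper <- normalized_counts(cc$n_hyper, cc$n_assessed)
      cc$norm_hypo <- normalized_counts(cc$n_hypo, cc$n_assessed)
      write_tsv(cc, file.path(d, "cpg_counts.tsv"))
      write_tsv(do.call(rbind, strata), file.path(d, "dmr_strata.tsv"))
    })
    done <- c(done, "dmr")
  }

  if ("phylo" %in% stages) {
    run_stage("phylo", {
      d <- file.path(outdir, "phylo"); dir.create(d, showWarnings = FALSE)
      pairs_all <- NULL; cors <- NULL
      lesions <- unique(stats::na.omit(samples[samples$role == "tumor",
                                               c("patient_id", "lesion_id")]))
      for (i in seq_len(nrow(lesions))) {
        pid <- lesions$patient_id[i]; lid <- lesions$lesion_id[i]
        sids <- samples$sample_id[samples$role == "tumor" &
                                    samples$patient_id == pid &
                                    samples$lesion_id == lid]
        nid <- samples$sample_id[samples$patient_id == pid &
                                   samples$role == "normal"][1L]
        if (length(sids) >= 2L) {
          dm <- methylation_distance(
            cohort$profiles[c(nid, sids)],
            min_reads = config$tree_min_reads, min_mad = config$tree_min_mad,
            regions = cohort$regions[["promoter"]])
          tr <- nj_tree(dm, root_label = nid)
          write_newick(tr, file.path(d, sprintf("%s_%s_meth.nwk", pid, lid)))
          if (length(sids) >= 3L) {
            gm <- mutation_distance(cohort$mutations[sids])
            gtr <- nj_tree(gm, root_label = sids[1L])
            write_newick(gtr, file.path(d, sprintf("%s_%s_mut.nwk", pid,
                                                   lid)))
          }
        }
        if (length(sids) >= 3L) {
          md <- methylation_distance(cohort$profiles[sids],
                                     min_reads = config$corr_min_reads,
                                     min_mad = config$corr_min_mad)
          gd <- mutation_distance(cohort$mutations[sids])
          mp <- normalize_pairwise(md); gp <- normalize_pairwise(gd)
          pr <- data.frame(patient_id = pid, lesion_id = lid,
                           from = mp$from, to = mp$to,
                           meth_norm = mp$normalized,
                           genetic_norm = gp$normalized,
                           stringsAsFactors = FALSE)
          pairs_all <- rbind(pairs_all, pr)
          if (nrow(pr) >= 3L) {
            cr <- distance_correlation(pr$genetic_norm, pr$meth_norm)
            cors <- rbind(cors, data.frame(
              patient_id = pid, lesion_id = lid, rho = cr$coefficient,
              n_pairs = cr$n, p_value = cr$p_value, stringsAsFactors = FALSE))
          }
        }
      }
      if (!is.null(pairs_all)) {
        write_tsv(pairs_all, file.path(d, "pair_distances.tsv"))
        cr_all <- distance_correlation(pairs_all$genetic_norm,
                                       pairs_all$meth_norm)
        cors <- rbind(cors, data.frame(
          patient_id = "pooled", lesion_id = "all", rho = cr_all$coefficient,
          n_pairs = cr_all$n, p_value = cr_all$p_value,
          stringsAsFactors = FALSE))
      }
      if (!is.null(cors)) write_tsv(cors, file.path(d, "correlations.tsv"))
    })
    done <- c(done, "phylo")
  }

  if ("context" %in% stages) {
    run_stage("context", {
      d <- file.path(outdir, "context"); dir.create(d, showWarnings = FALSE)
      l1 <- cohort$regions[["LINE1"]]
      rows <- lapply(tumors, function(sid) {
        muts <- cohort$mutations[[sid]]
        tmb <- if (!is.null(muts)) length(muts$variants) else NA_integer_
        lids <- samples$sample_id[samples$role == "tumor" &
                                    samples$lesion_id == lesion_of(sid) &
                                    samples$patient_id ==
                                    samples$patient_id[samples$sample_id == sid]]
        clonal <- NA_real_
        if (!is.null(muts) && length(muts$variants)) {
          shared <- Reduce(intersect,
                           lapply(cohort$mutations[lids],
                                  function(m) m$variants))
          clonal <- length(shared) / length(muts$variants)
        }
        data.frame(sample_id = sid, stage = stage_of(sid),
                   line1_beta = line1_methylation(
                     cohort$profiles[[sid]], l1,
                     min_reads = config$line1_min_reads),
                   tmb = tmb, log2_tmb = log2(tmb + 1),
                   clonal_fraction = clonal, stringsAsFactors = FALSE)
      })
      bt <- do.call(rbind, rows)
      ## include per-patient normals as the NORMAL stage reference
      nrows <- lapply(samples$sample_id[samples$role == "normal"],
                      function(sid) {
                        data.frame(sample_id = sid, stage = "NORMAL",
                                   line1_beta = line1_methylation(
                                     cohort$profiles[[sid]], l1,
                                     min_reads = config$line1_min_reads),
                                   tmb = 0L, log2_tmb = 0,
                                   clonal_fraction = NA_real_,
                                   stringsAsFactors = FALSE)
                      })
      bt <- rbind(bt, do.call(rbind, nrows))
      write_tsv(bt, file.path(d, "line1_burden.tsv"))
      tb <- bt[bt$stage != "NORMAL", , drop = FALSE]
      cr <- burden_correlation(tb$line1_beta, tb$log2_tmb)
      crc <- data.frame(pair = "line1_vs_log2_tmb", rho = cr$coefficient,
                        n = cr$n, p_value = cr$p_value,
                        stringsAsFactors = FALSE)
      if (any(!is.na(tb$clonal_fraction)) &&
          stats::sd(tb$clonal_fraction, na.rm = TRUE) > 0) {
        ok <- !is.na(tb$clonal_fraction)
        cr2 <- burden_correlation(tb$line1_beta[ok], tb$clonal_fraction[ok])
        crc <- rbind(crc, data.frame(pair = "line1_vs_clonal_fraction",
                                     rho = cr2$coefficient, n = cr2$n,
                                     p_value = cr2$p_value,
                                     stringsAsFactors = FALSE))
      }
      write_tsv(crc, file.path(d, "burden_correlations.tsv"))
      if (!is.null(all_records) && length(all_records)) {
        tssd <- do.call(rbind, lapply(names(all_records), function(sid) {
          r <- all_records[[sid]]
          el <- r[r$is_elocus, , drop = FALSE]
          if (nrow(el) == 0L) return(NULL)
          data.frame(sample_id = sid, stage = stage_of(sid),
                     chrom = el$chrom, pos1 = el$pos1, pos4 = el$pos4,
                     tss_distance = nearest_tss_distance(
                       el, cohort$regions[["TSS"]]),
                     stringsAsFactors = FALSE)
        }))
        if (!is.null(tssd)) write_tsv(tssd, file.path(d,
                                                      "tss_distances.tsv"))
        enr <- NULL
        pooled <- do.call(rbind, lapply(names(all_records), function(sid) {
          add_cols(all_records[[sid]], stage = stage_of(sid))
        }))
        for (stg in unique(pooled$stage)) {
          ps <- pooled[pooled$stage == stg, , drop = FALSE]
          bg <- unique(data.frame(chrom = ps$chrom, start = ps$pos1,
                                  end = ps$pos4, stringsAsFactors = FALSE))
          qs <- unique(data.frame(chrom = ps$chrom[ps$is_elocus],
                                  start = ps$pos1[ps$is_elocus],
                                  end = ps$pos4[ps$is_elocus],
                                  stringsAsFactors = FALSE))
          if (nrow(qs) == 0L) next
          er <- regionset_enrichment(qs, bg, strat_sets)
          enr <- rbind(enr, add_cols(er, stage = stg))
        }
        if (!is.null(enr)) write_tsv(enr, file.path(d, "enrichment.tsv"))
      }
    })
    done <- c(done, "context")
  }

  if ("report" %in% stages) {
    run_stage("report", {
      d <- file.path(outdir, "report"); dir.create(d, showWarnings = FALSE)
      ## pairwise Pearson correlation of each tumor against its normal
      pc <- do.call(rbind, lapply(tumors, function(sid) {
        nid <- normal_of(sid)
        a <- cohort$profiles[[sid]]$sites
        b <- cohort$profiles[[nid]]$sites
        a <- a[a$total >= config$min_reads_cpg, ]
        b <- b[b$total >= config$min_reads_cpg, ]
        sh <- intersect(paste(a$chrom, a$pos), paste(b$chrom, b$pos))
        ba <- a$beta[match(sh, paste(a$chrom, a$pos))]
        bb <- b$beta[match(sh, paste(b$chrom, b$pos))]
        ct <- stats::cor.test(ba, bb, method = "pearson")
        data.frame(sample_id = sid, stage = stage_of(sid),
                   r = unname(ct$estimate), n_cpgs = length(sh),
                   p_value = ct$p.value, stringsAsFactors = FALSE)
      }))
      write_tsv(pc, file.path(d, "pearson_correlations.tsv"))
      ## 5-kb tile matrix over tiles shared by all samples -> PCA
      tl <- lapply(cohort$profiles, aggregate_tiles,
                   tile_size = config$tile_size,
                   min_reads = config$min_reads_cpg)
      keys <- Reduce(intersect, lapply(tl, function(t)
        paste(t$chrom, t$tile_start)))
      if (length(keys) >= 3L) {
        M <- vapply(tl, function(t)
          t$mean_beta[match(keys, paste(t$chrom, t$tile_start))],
          numeric(length(keys)))
        pca <- stats::prcomp(t(M), center = TRUE, scale. = FALSE)
        k <- min(4L, ncol(pca$x))
        coords <- data.frame(sample_id = rownames(pca$x),
                             stage = as.character(
                               stage_of(rownames(pca$x))),
                             pca$x[, seq_len(k), drop = FALSE],
                             stringsAsFactors = FALSE)
        write_tsv(coords, file.path(d, "pca_coordinates.tsv"))
      }
      ## hierarchical clustering on deeply covered single CpGs
      prof_keys <- lapply(cohort$profiles, function(p) {
        s <- p$sites[p$sites$total >= config$cluster_min_reads, ]
        paste(s$chrom, s$pos)
      })
      shared <- Reduce(intersect, prof_keys)
      if (length(shared) >= 3L) {
        B <- vapply(cohort$profiles, function(p) {
          k <- paste(p$sites$chrom, p$sites$pos)
          p$sites$beta[match(shared, k)]
        }, numeric(length(shared)))
        hc <- stats::hclust(stats::dist(t(B)), method = "ward.D2")
        write_newick(ape::as.phylo(hc), file.path(d, "dendrogram.nwk"))
      }
      ## ECDF evaluation grids for delta-S by stage
      if (!is.null(all_records) && length(all_records)) {
        pooled <- do.call(rbind, lapply(names(all_records), function(sid) {
          data.frame(stage = stage_of(sid),
                     delta_S = all_records[[sid]]$delta_S,
                     stringsAsFactors = FALSE)
        }))
        grid <- seq(-100, 100, by = 1)
        ec <- do.call(rbind, lapply(split(pooled$delta_S, pooled$stage),
                                    function(v) shift_ecdf(v)(grid)))
        df <- data.frame(stage = rownames(ec), ec, check.names = FALSE,
                         stringsAsFactors = FALSE)
        names(df) <- c("stage", sprintf("x_%d", grid))
        write_tsv(df, file.path(d, "delta_s_ecdf.tsv"))
        grDevices::pdf(file.path(d, "delta_s_ecdf.pdf"), width = 6,
                       height = 4)
        plot(NULL, xlim = c(-100, 20), ylim = c(0, 1),
             xlab = expression(Delta * S), ylab = "cumulative fraction",
             main = "Epiallele shift ECDF by stage")
        stg <- sort(unique(pooled$stage))
        for (z in seq_along(stg)) {
          v <- pooled$delta_S[pooled$stage == stg[z]]
          graphics::lines(sort(v), seq_along(sort(v)) / length(v), col = z)
        }
        graphics::legend("topleft", legend = stg, col = seq_along(stg),
                         lty = 1, bty = "n")
        grDevices::dev.off()
      }
    })
    done <- c(done, "report")
  }

  ## manifest: every parameter + md5 of every text output (figures exempt)
  outs <- list.files(outdir, recursive = TRUE, full.names = TRUE,
                     pattern = "\\.(tsv|csv|cov|bed|nwk|json)$")
  outs <- outs[basename(outs) != "manifest.json"]
  manifest <- list(
    package = "methevo",
    version = as.character(utils::packageVersion("methevo")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), c("outdir"))],
    stages_completed = unique(done),
    files = as.list(stats::setNames(
      unname(tools::md5sum(outs)),
      substring(outs, nchar(sub("/+$", "", outdir)) + 2L))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outdir = outdir, manifest = manifest, cohort = cohort))
}
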