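#' Stage presets for the synthetic cohort generator
#'
#' Returns the generating parameters for one histologic stage of the
#' synthetic staged cohort. The defaults encode the qualitative trends the
#' generator is built to emulate: hypermethylation events appear from AAH
#' onward and grow with stage; hypomethylation appears only from AIS
#' onward; epiallele diversity (lower `dirichlet_alpha` = weaker pull
#' toward the ancestral epiallele = more diversity) increases with stage;
#' LINE-1 methylation loss (`line1_delta`) and mutation counts increase
#' with stage.
#'
#' @param stage one of [stage_levels()].
#' @param ... named overrides of individual parameters.
#' @return List of class `stage_params`: `stage`, `n_gain_dmrs`,
#'   `n_loss_dmrs`, `dirichlet_alpha`, `line1_delta`, `n_trunk_mut`,
#'   `n_private_mut`, `coupling` (the fraction lambda of private
#'   methylation-event load assigned on clone-tree branches shared with
#'   mutations).
#' @export
stage_params <- function(stage, ...) {
  stage <- match.arg(toupper(stage), stage_levels())
  defaults <- list(
    NORMAL = list(n_gain_dmrs = 0L, n_loss_dmrs = 0L, dirichlet_alpha = 300,
                  line1_delta = 0, n_trunk_mut = 0L, n_private_mut = 0L,
                  coupling = 0),
    AAH = list(n_gain_dmrs = 6L, n_loss_dmrs = 0L, dirichlet_alpha = 80,
               line1_delta = 0.02, n_trunk_mut = 20L, n_private_mut = 8L,
               coupling = 0.5),
    AIS = list(n_gain_dmrs = 14L, n_loss_dmrs = 8L, dirichlet_alpha = 30,
               line1_delta = 0.06, n_trunk_mut = 40L, n_private_mut = 15L,
               coupling = 0.5),
    MIA = list(n_gain_dmrs = 20L, n_loss_dmrs = 16L, dirichlet_alpha = 18,
               line1_delta = 0.10, n_trunk_mut = 70L, n_private_mut = 25L,
               coupling = 0.5),
    ADC = list(n_gain_dmrs = 26L, n_loss_dmrs = 24L, dirichlet_alpha = 8,
               line1_delta = 0.15, n_trunk_mut = 120L, n_private_mut = 40L,
               coupling = 0.5)
  )[[stage]]
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown stage parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  p <- c(list(stage = stage), defaults)
  stopifnot(p$n_gain_dmrs >= 0, p$n_loss_dmrs >= 0, p$dirichlet_alpha > 0,
            p$line1_delta >= 0, p$line1_delta <= 1,
            p$n_trunk_mut >= 0, p$n_private_mut >= 0,
            p$coupling >= 0, p$coupling <= 1)
  class(p) <- "stage_params"
  p
}

## segment plan for one cassette of the synthetic genome
cassette_plan <- function(layout) {
  if (layout == "island") {
    data.frame(type = "promoter", len = 1600L, n_win = 3L, n_single = 10L,
               class = "island", stringsAsFactors = FALSE)
  } else {
    data.frame(
      type = c("promoter", "enhancer", "transcribed", "heterochromatin",
               "repeat"),
      len = c(1100L, 800L, 3000L, 2400L, 800L),
      n_win = c(2L, 1L, 1L, 2L, 0L),
      n_single = c(8L, 2L, 4L, 4L, 4L),
      class = c("island", "high", "high", "high", "high"),
      stringsAsFactors = FALSE)
  }
}

#' Simulate a normal-lung RRBS methylome on a synthetic genome
#'
#' Lays out a single synthetic chromosome as a sequence of cassettes of
#' regulatory segments (promoter CpG islands, enhancers, transcribed
#' regions, heterochromatin, repeats, with LINE-1 elements in alternating
#' repeat segments and a PMD covering the second half of the genome), and
#' draws a normal methylome over it: beta from a bimodal mixture (low-beta
#' promoter islands, high-beta background, LINE-1 around 0.85), coverage
#' negative-binomial with mean 60 and dispersion 0.3 floored at 10 reads,
#' and concentrated (near-monoclonal) epiallele distributions at the 4-CpG
#' windows. Deterministic given the seed.
#'
#' @param n_cpgs total number of CpG sites (>= 100).
#' @param n_windows number of 4-CpG epiallele windows (each consumes 4 of
#'   the `n_cpgs`; their span is kept under 100 bp so the four CpGs fit on
#'   one read).
#' @param seed integer RNG seed.
#' @param layout `"mixed"` (default cassette mix) or `"island"`
#'   (promoter-island-only genome).
#' @param coverage_mean,coverage_disp,coverage_floor negative-binomial
#'   coverage model (variance = mu + disp * mu^2), floored.
#' @param sample_id,patient_id identifiers for the returned profile.
#' @return List of class `normal_methylome`: `profile` ([meth_profile()]),
#'   `epialleles` ([epiallele_table()]), `regions` (named list of
#'   [region_set()]: promoter, enhancer, transcribed, heterochromatin,
#'   repeat, LINE1, PMD, TSS), and `truth` (per-CpG true betas and classes,
#'   window table with dominant patterns, genome length).
#' @export
simulate_normal_methylome <- function(n_cpgs = 2400L, n_windows = 240L,
                                      seed = 1L, layout = c("mixed", "island"),
                                      coverage_mean = 60, coverage_disp = 0.3,
                                      coverage_floor = 10L,
                                      sample_id = "N", patient_id = "P0") {
  layout <- match.arg(layout)
  stopifnot(n_cpgs >= 100L, n_windows >= 0L)
  if (4L * n_windows > n_cpgs) {
    stop("n_cpgs = ", n_cpgs, " too small to host ", n_windows,
         " 4-CpG windows")
  }
  set.seed(as.integer(seed))
  plan <- cassette_plan(layout)
  w_left <- as.integer(n_windows)
  s_left <- as.integer(n_cpgs - 4L * n_windows)
  pos <- integer(0); cls <- character(0); win_of <- integer(0)
  win_rows <- list(); seg_rows <- list()
  cassette_starts <- integer(0)
  cursor_genome <- 1L
  cassette <- 0L
  while (w_left > 0L || s_left > 0L) {
    cassette <- cassette + 1L
    cassette_starts <- c(cassette_starts, cursor_genome)
    for (si in seq_len(nrow(plan))) {
      seg_start <- cursor_genome
      cur <- seg_start + 30L
      wk <- min(plan$n_win[si], w_left)
      sk <- min(plan$n_single[si], s_left)
      seg_class <- plan$class[si]
      if (plan$type[si] == "repeat" && cassette %% 2L == 1L) {
        seg_class <- "line1"
      }
      for (w in seq_len(wk)) {
        offs <- cumsum(c(0L, sample(8:25, 3L, replace = TRUE)))
        wpos <- cur + offs
        win_rows[[length(win_rows) + 1L]] <-
          data.frame(chrom = "chr1", pos1 = wpos[1], pos2 = wpos[2],
                     pos3 = wpos[3], pos4 = wpos[4], class = seg_class,
                     stringsAsFactors = FALSE)
        pos <- c(pos, wpos)
        cls <- c(cls, rep(seg_class, 4L))
        win_of <- c(win_of, rep(length(win_rows), 4L))
        cur <- wpos[4] + sample(70:130, 1L)
      }
      w_left <- w_left - wk
      for (s in seq_len(sk)) {
        pos <- c(pos, cur)
        cls <- c(cls, seg_class)
        win_of <- c(win_of, NA_integer_)
        cur <- cur + sample(35:85, 1L)
      }
      s_left <- s_left - sk
      seg_end <- max(seg_start + plan$len[si] - 1L, cur + 20L)
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(type = plan$type[si], start = seg_start, end = seg_end,
                   cassette = cassette, line1 = seg_class == "line1",
                   stringsAsFactors = FALSE)
      cursor_genome <- seg_end + 250L
    }
    cursor_genome <- cursor_genome + 1000L
  }
  segs <- do.call(rbind, seg_rows)
  genome_length <- max(segs$end) + 1000L
  segs$n_cpgs <- vapply(seq_len(nrow(segs)), function(i)
    sum(pos >= segs$start[i] & pos <= segs$end[i]), integer(1))
  segs$cpg_span <- vapply(seq_len(nrow(segs)), function(i) {
    p <- pos[pos >= segs$start[i] & pos <= segs$end[i]]
    if (length(p) < 2L) 0L else as.integer(diff(range(p)))
  }, integer(1))
  n <- length(pos)
  beta_true <- numeric(n)
  beta_true[cls == "island"] <- stats::rbeta(sum(cls == "island"), 1.5, 15)
  beta_true[cls == "high"] <- stats::rbeta(sum(cls == "high"), 12, 2.2)
  beta_true[cls == "line1"] <- stats::rbeta(sum(cls == "line1"), 30, 5.3)
  total <- pmax(coverage_floor,
                stats::rnbinom(n, mu = coverage_mean,
                               size = 1 / coverage_disp))
  meth <- stats::rbinom(n, total, beta_true)
  profile <- meth_profile(
    data.frame(chrom = "chr1", pos = pos, meth = meth, total = total,
               stringsAsFactors = FALSE),
    sample_id = sample_id, patient_id = patient_id, stage = "NORMAL",
    role = "normal")
  windows <- if (length(win_rows)) do.call(rbind, win_rows) else
    data.frame(chrom = character(0), pos1 = integer(0), pos2 = integer(0),
               pos3 = integer(0), pos4 = integer(0), class = character(0))
  ## dominant ancestral epiallele per window: fully unmethylated for island
  ## windows, fully methylated elsewhere
  windows$dominant <- ifelse(windows$class == "island", "0000", "1111")
  epi <- draw_epialleles(windows, conc = 300, spread = 0.3,
                         sample_id = sample_id)
  make_rs <- function(type) {
    sub <- segs[segs$type == type, , drop = FALSE]
    region_set(rep("chr1", nrow(sub)), sub$start, sub$end, name = type)
  }
  line1 <- segs[segs$line1, , drop = FALSE]
  proms <- segs[segs$type == "promoter", , drop = FALSE]
  pmd_from <- cassette_starts[max(1L, floor(cassette / 2) + 1L)]
  regions <- list(
    promoter = make_rs("promoter"),
    enhancer = make_rs("enhancer"),
    transcribed = make_rs("transcribed"),
    heterochromatin = make_rs("heterochromatin"),
    repeat_ = {
      r <- make_rs("repeat"); attr(r, "name") <- "repeat"; r
    },
    LINE1 = region_set(rep("chr1", nrow(line1)), line1$start, line1$end,
                       name = "LINE1"),
    PMD = region_set("chr1", pmd_from, genome_length, name = "PMD"),
    TSS = region_set(rep("chr1", nrow(proms)), proms$start + 1000L,
                     proms$start + 1000L, strand = "+", name = "TSS")
  )
  structure(
    list(profile = profile, epialleles = epi, regions = regions,
         truth = list(
           sites = data.frame(chrom = "chr1", pos = pos, beta = beta_true,
                              class = cls, window = win_of,
                              stringsAsFactors = FALSE),
           windows = windows, segments = segs,
           genome_length = genome_length,
           coverage = list(mean = coverage_mean, disp = coverage_disp,
                           floor = coverage_floor))),
    class = "normal_methylome")
}

## Draw epiallele count tables for a window table with a `dominant` column.
## Pattern probabilities ~ Dirichlet(conc * e_dominant + spread): the
## concentration pulls mass onto the ancestral pattern over a flat base, so
## lower conc gives more diverse (higher-entropy) epiallele distributions.
draw_epialleles <- function(windows, conc, spread, sample_id) {
  nw <- nrow(windows)
  counts <- matrix(0L, nw, 16L, dimnames = list(NULL, epiallele_patterns()))
  if (nw) {
    dom_idx <- match(windows$dominant, epiallele_patterns())
    totals <- 60L + stats::rnbinom(nw, mu = 20, size = 4)
    for (i in seq_len(nw)) {
      alpha <- rep(spread, 16L)
      alpha[dom_idx[i]] <- alpha[dom_idx[i]] + conc
      p <- rdirichlet1(alpha)
      counts[i, ] <- stats::rmultinom(1L, totals[i], p)[, 1L]
    }
  }
  epiallele_table(windows[, c("chrom", "pos1", "pos2", "pos3", "pos4"),
                          drop = FALSE],
                  counts, sample_id = sample_id)
}

## resample coverage + epialleles for a fresh normal specimen on the same
## synthetic genome truth (used to give each patient its own normal)
resample_normal <- function(normal, seed, sample_id, patient_id) {
  set.seed(as.integer(seed))
  tr <- normal$truth
  n <- nrow(tr$sites)
  total <- pmax(tr$coverage$floor,
                stats::rnbinom(n, mu = tr$coverage$mean,
                               size = 1 / tr$coverage$disp))
  meth <- stats::rbinom(n, total, tr$sites$beta)
  profile <- meth_profile(
    data.frame(chrom = tr$sites$chrom, pos = tr$sites$pos, meth = meth,
               total = total, stringsAsFactors = FALSE),
    sample_id = sample_id, patient_id = patient_id, stage = "NORMAL",
    role = "normal")
  epi <- draw_epialleles(tr$windows, conc = 300, spread = 0.3,
                         sample_id = sample_id)
  list(profile = profile, epialleles = epi)
}

#' Simulate a staged lesion with multi-region specimens
#'
#' Plants stage-dependent methylation aberrations on top of a synthetic
#' normal methylome and draws one or more spatially separated tumor-region
#' specimens descending from a simple two-level clone tree (a shared trunk
#' plus one private branch per region):
#' \itemize{
#'   \item gain DMRs: beta shifted up by at least 0.4 inside randomly
#'     chosen promoter-island segments (trunk events, shared by all
#'     regions);
#'   \item loss DMRs: beta shifted down by at least 0.4 inside high-beta
#'     heterochromatin segments (trunk events);
#'   \item private methylation events: per-region beta shifts of magnitude
#'     0.65 in additional segments (hypermethylation in unused promoters
#'     when the stage plants no losses, hypomethylation in enhancer or
#'     transcribed segments otherwise); their number per region follows the
#'     clone-tree coupling lambda: a lambda fraction of the event load
#'     scales with the region's private mutation load, the rest is
#'     independent;
#'   \item epiallele counts: Dirichlet-multinomial with the stage's
#'     concentration `dirichlet_alpha` toward the ancestral pattern (lower
#'     = more diverse = more entropy shift relative to normal);
#'   \item LINE-1 CpGs: true beta reduced by `line1_delta`;
#'   \item mutations: `n_trunk_mut` trunk variants shared by all regions
#'     plus per-region private variants.
#' }
#'
#' @param normal a `normal_methylome` from [simulate_normal_methylome()].
#' @param params a [stage_params()] preset.
#' @param n_regions number of spatially separated specimens (>= 1).
#' @param seed integer RNG seed.
#' @param patient_id,lesion_id identifiers; specimen sample ids are
#'   `<patient>_<lesion>_R<k>`.
#' @return List of class `lesion_sim`: `specimens` (list per region with
#'   `profile`, `epialleles`, `mutations`) and `truth` (planted gain/loss
#'   DMR region sets, per-region private events, clone-tree loads,
#'   mutation sets, expected LINE-1 mean, the params).
#' @export
simulate_lesion <- function(normal, params, n_regions = 1L, seed = 1L,
                            patient_id = "P1", lesion_id = "L1") {
  stopifnot(inherits(normal, "normal_methylome"), n_regions >= 1L)
  set.seed(as.integer(seed))
  tr <- normal$truth
  segs <- tr$segments
  ## events are planted only in segments dense enough (>= 4 CpGs over
  ## >= 50 bp) to be recoverable by a CpG-count-gated DMR caller
  hostable <- segs$n_cpgs >= 4L & segs$cpg_span >= 50L
  proms <- which(segs$type == "promoter" & hostable)
  hets <- which(segs$type == "heterochromatin" & hostable)
  others <- which(segs$type %in% c("enhancer", "transcribed") & hostable)
  if (params$n_gain_dmrs > length(proms)) {
    stop("requested ", params$n_gain_dmrs, " gain DMRs but only ",
         length(proms), " promoter host segments exist")
  }
  if (params$n_loss_dmrs > length(hets)) {
    stop("requested ", params$n_loss_dmrs, " loss DMRs but only ",
         length(hets), " heterochromatin host segments exist")
  }
  gain_hosts <- if (params$n_gain_dmrs)
    sort(sample(proms, params$n_gain_dmrs)) else integer(0)
  loss_hosts <- if (params$n_loss_dmrs)
    sort(sample(hets, params$n_loss_dmrs)) else integer(0)
  ## trunk beta shifts, shared by every region of the lesion
  base_beta <- tr$sites$beta
  trunk_beta <- base_beta
  in_seg <- function(i) tr$sites$pos >= segs$start[i] &
    tr$sites$pos <= segs$end[i]
  for (i in gain_hosts) {
    trunk_beta[in_seg(i)] <- pmin(0.98, base_beta[in_seg(i)] +
                                    0.4 + stats::runif(1, 0, 0.25))
  }
  for (i in loss_hosts) {
    trunk_beta[in_seg(i)] <- pmax(0.02, base_beta[in_seg(i)] -
                                    (0.4 + stats::runif(1, 0, 0.25)))
  }
  l1 <- tr$sites$class == "line1"
  trunk_beta[l1] <- pmax(0.02, trunk_beta[l1] - params$line1_delta)
  ## clone-tree loads: r drives private mutations; private methylation
  ## event counts follow lambda * r + (1 - lambda) * independent s
  r <- stats::runif(n_regions, 0.4, 1.6)
  s <- stats::runif(n_regions, 0.4, 1.6)
  n_priv_mut <- if (params$n_private_mut > 0)
    pmax(1L, round(params$n_private_mut * r)) else rep(0L, n_regions)
  m_base <- if (params$n_private_mut > 0)
    max(1, round(0.35 * params$n_private_mut)) else 0
  n_priv_meth <- if (m_base > 0)
    pmax(1L, round(m_base * (params$coupling * r +
                               (1 - params$coupling) * s)))
  else rep(0L, n_regions)
  priv_dir <- if (params$n_loss_dmrs == 0L) "gain" else "loss"
  priv_pool <- if (priv_dir == "gain") setdiff(proms, gain_hosts) else others
  ## assign private event host segments, distinct across regions while the
  ## pool lasts
  priv_hosts <- vector("list", n_regions)
  pool <- priv_pool
  for (k in seq_len(n_regions)) {
    take <- n_priv_meth[k]
    if (take == 0L) { priv_hosts[[k]] <- integer(0); next }
    if (length(pool) >= take) {
      priv_hosts[[k]] <- sort(sample(pool, take))
      pool <- setdiff(pool, priv_hosts[[k]])
    } else {
      priv_hosts[[k]] <- sort(sample(priv_pool, take))
    }
  }
  ## mutations
  all_pos <- sample(tr$genome_length,
                    params$n_trunk_mut + sum(n_priv_mut))
  bases <- c("A", "C", "G", "T")
  mk_var <- function(p) {
    ref <- sample(bases, length(p), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    variant_key("chr1", p, ref, alt)
  }
  trunk_mut <- if (params$n_trunk_mut)
    mk_var(all_pos[seq_len(params$n_trunk_mut)]) else character(0)
  off <- params$n_trunk_mut
  priv_mut <- vector("list", n_regions)
  for (k in seq_len(n_regions)) {
    priv_mut[[k]] <- if (n_priv_mut[k])
      mk_var(all_pos[off + seq_len(n_priv_mut[k])]) else character(0)
    off <- off + n_priv_mut[k]
  }
  ## per-region specimens
  specimens <- vector("list", n_regions)
  priv_events <- vector("list", n_regions)
  n <- nrow(tr$sites)
  for (k in seq_len(n_regions)) {
    beta_k <- trunk_beta
    ev <- priv_hosts[[k]]
    for (i in ev) {
      idx <- in_seg(i)
      if (priv_dir == "gain") {
        beta_k[idx] <- pmin(0.98, trunk_beta[idx] + 0.65)
      } else {
        beta_k[idx] <- pmax(0.02, trunk_beta[idx] - 0.65)
      }
    }
    priv_events[[k]] <- if (length(ev)) {
      region_set(rep("chr1", length(ev)), segs$start[ev], segs$end[ev],
                 name = paste0("private_", priv_dir))
    } else {
      region_set(character(0), integer(0), integer(0),
                 name = paste0("private_", priv_dir))
    }
    beta_k[l1] <- pmin(0.98, pmax(
      0.02, beta_k[l1] + stats::rnorm(sum(l1), 0, 0.01)))
    total <- pmax(tr$coverage$floor,
                  stats::rnbinom(n, mu = tr$coverage$mean,
                                 size = 1 / tr$coverage$disp))
    meth <- stats::rbinom(n, total, beta_k)
    sid <- sprintf("%s_%s_R%d", patient_id, lesion_id, k)
    profile <- meth_profile(
      data.frame(chrom = tr$sites$chrom, pos = tr$sites$pos, meth = meth,
                 total = total, stringsAsFactors = FALSE),
      sample_id = sid, patient_id = patient_id, lesion_id = lesion_id,
      stage = params$stage, role = "tumor")
    epi <- draw_epialleles(tr$windows, conc = params$dirichlet_alpha,
                           spread = 1, sample_id = sid)
    specimens[[k]] <- list(
      profile = profile, epialleles = epi,
      mutations = mutation_profile(sid, c(trunk_mut, priv_mut[[k]])))
  }
  names(specimens) <- vapply(specimens, function(x) x$profile$sample_id,
                             character(1))
  mk_dmr_rs <- function(hosts, nm) {
    region_set(rep("chr1", length(hosts)), segs$start[hosts],
               segs$end[hosts], name = nm)
  }
  truth <- list(
    gain_dmrs = mk_dmr_rs(gain_hosts, "planted_gain"),
    loss_dmrs = mk_dmr_rs(loss_hosts, "planted_loss"),
    private_events = priv_events,
    private_direction = priv_dir,
    clone_loads = data.frame(region = seq_len(n_regions), r = r, s = s,
                             n_private_mut = n_priv_mut,
                             n_private_meth = n_priv_meth),
    trunk_mutations = trunk_mut, private_mutations = priv_mut,
    line1_expected = mean(pmax(0.02, tr$sites$beta[l1] - params$line1_delta)),
    params = params, seed = seed)
  structure(list(specimens = specimens, truth = truth),
            class = "lesion_sim")
}

#' Planted differential-methylation truth for one region specimen
#'
#' Returns all intervals where the generator shifted beta for the given
#' region: the lesion's trunk gain/loss DMRs plus that region's private
#' events, with their directions — the ground truth against which called
#' DMRs are scored.
#'
#' @param lesion a `lesion_sim` from [simulate_lesion()].
#' @param region region index (default 1).
#' @return data.frame `chrom`, `start`, `end`, `direction`.
#' @export
planted_dmrs <- function(lesion, region = 1L) {
  tr <- lesion$truth
  g <- tr$gain_dmrs; l <- tr$loss_dmrs; p <- tr$private_events[[region]]
  out <- rbind(
    if (nrow(g)) data.frame(chrom = g$chrom, start = g$start, end = g$end,
                            direction = "gain", stringsAsFactors = FALSE),
    if (nrow(l)) data.frame(chrom = l$chrom, start = l$start, end = l$end,
                            direction = "loss", stringsAsFactors = FALSE),
    if (nrow(p)) data.frame(chrom = p$chrom, start = p$start, end = p$end,
                            direction = tr$private_direction,
                            stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Default synthetic cohort configuration
#'
#' Three patients, each carrying one lesion per stage (AAH, AIS, MIA, ADC);
#' the first patient's lesions are profiled in four spatially separated
#' regions (so phylogenetic analyses have enough taxa), the others in one.
#'
#' @param n_patients number of patients.
#' @param stages stage labels per lesion.
#' @param multi_region_patient index of the patient profiled multi-region
#'   (0 for none).
#' @param n_regions regions per lesion for the multi-region patient.
#' @param n_cpgs,n_windows,layout genome parameters, see
#'   [simulate_normal_methylome()].
#' @return Config list consumable by [simulate_cohort()].
#' @export
default_cohort_config <- function(n_patients = 3L,
                                  stages = c("AAH", "AIS", "MIA", "ADC"),
                                  multi_region_patient = 1L, n_regions = 4L,
                                  n_cpgs = 2400L, n_windows = 240L,
                                  layout = "mixed") {
  patients <- lapply(seq_len(n_patients), function(i) {
    list(patient_id = sprintf("P%d", i),
         lesions = lapply(seq_along(stages), function(j) {
           list(lesion_id = sprintf("L%d", j), stage = stages[j],
                n_regions = if (i == multi_region_patient) n_regions else 1L)
         }))
  })
  list(genome = list(n_cpgs = n_cpgs, n_windows = n_windows, layout = layout),
       patients = patients)
}

#' Simulate a full staged cohort and write it to disk
#'
#' Generates one synthetic genome, a per-patient normal specimen and the
#' configured staged lesions, and writes the complete file bundle in the
#' package's interchange formats: Bismark-style coverage files, epiallele
#' pattern TSVs, region BEDs, a mutation TSV, a sample sheet CSV and a JSON
#' manifest with per-file MD5 checksums and a ground-truth summary.
#' Deterministic: identical (config, seed) produce byte-identical files.
#'
#' @param config cohort configuration, see [default_cohort_config()].
#' @param seed integer RNG seed.
#' @param outdir output directory (created if needed); `NULL` to skip
#'   writing and return only in-memory objects.
#' @return Invisibly, a list: `normal` (the genome/normal methylome),
#'   `patients` (per patient: `normal` specimen and `lesions` of class
#'   `lesion_sim`), `samples` (sample sheet data.frame), `manifest`.
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            outdir = NULL) {
  seed <- as.integer(seed)
  g <- config$genome
  genome <- simulate_normal_methylome(
    n_cpgs = g$n_cpgs %||% 2400L, n_windows = g$n_windows %||% 240L,
    seed = sub_seed(seed, 1L), layout = g$layout %||% "mixed")
  sheet <- list(); patients <- list()
  sample_ids <- character(0)
  for (i in seq_along(config$patients)) {
    pc <- config$patients[[i]]
    pid <- pc$patient_id
    nid <- sprintf("%s_N", pid)
    norm_i <- resample_normal(genome, seed = sub_seed(seed, 100L + i),
                              sample_id = nid, patient_id = pid)
    sheet[[length(sheet) + 1L]] <- data.frame(
      sample_id = nid, patient_id = pid, lesion_id = NA_character_,
      stage = "NORMAL", role = "normal", stringsAsFactors = FALSE)
    sample_ids <- c(sample_ids, nid)
    lesions <- list()
    for (j in seq_along(pc$lesions)) {
      lc <- pc$lesions[[j]]
      les <- simulate_lesion(
        genome, stage_params(lc$stage),
        n_regions = lc$n_regions %||% 1L,
        seed = sub_seed(seed, 10000L + 97L * i + j),
        patient_id = pid, lesion_id = lc$lesion_id)
      for (sp in les$specimens) {
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = sp$profile$sample_id, patient_id = pid,
          lesion_id = lc$lesion_id, stage = lc$stage, role = "tumor",
          stringsAsFactors = FALSE)
      }
      sample_ids <- c(sample_ids, names(les$specimens))
      lesions[[lc$lesion_id]] <- les
    }
    patients[[pid]] <- list(normal = norm_i, lesions = lesions)
  }
  if (anyDuplicated(sample_ids)) {
    stop("conflicting sample ids in cohort config: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  samples <- do.call(rbind, sheet)
  manifest <- list(seed = seed, config = config,
                   n_samples = nrow(samples),
                   genome_length = genome$truth$genome_length)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "coverage"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outdir, "patterns"), showWarnings = FALSE)
    dir.create(file.path(outdir, "regions"), showWarnings = FALSE)
    files <- character(0)
    for (nm in names(genome$regions)) {
      f <- file.path(outdir, "regions",
                     paste0(attr(genome$regions[[nm]], "name"), ".bed"))
      write_bed(genome$regions[[nm]], f)
      files <- c(files, f)
    }
    muts <- list()
    for (pid in names(patients)) {
      pat <- patients[[pid]]
      f <- file.path(outdir, "coverage",
                     paste0(pat$normal$profile$sample_id, ".cov"))
      write_coverage(pat$normal$profile, f)
      files <- c(files, f)
      f <- file.path(outdir, "patterns",
                     paste0(pat$normal$profile$sample_id, ".tsv"))
      write_patterns(pat$normal$epialleles, f)
      files <- c(files, f)
      for (les in pat$lesions) {
        for (sp in les$specimens) {
          f <- file.path(outdir, "coverage",
                         paste0(sp$profile$sample_id, ".cov"))
          write_coverage(sp$profile, f)
          files <- c(files, f)
          f <- file.path(outdir, "patterns",
                         paste0(sp$profile$sample_id, ".tsv"))
          write_patterns(sp$epialleles, f)
          files <- c(files, f)
          muts[[sp$profile$sample_id]] <- sp$mutations
        }
      }
    }
    f <- file.path(outdir, "mutations.tsv")
    write_mutations(muts, f)
    files <- c(files, f)
    f <- file.path(outdir, "samples.csv")
    utils::write.csv(samples, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    truth_summary <- lapply(names(patients), function(pid) {
      lapply(patients[[pid]]$lesions, function(les) {
        list(stage = les$truth$params$stage,
             n_gain_dmrs = nrow(les$truth$gain_dmrs),
             n_loss_dmrs = nrow(les$truth$loss_dmrs),
             n_trunk_mut = length(les$truth$trunk_mutations),
             line1_expected = les$truth$line1_expected)
      })
    })
    names(truth_summary) <- names(patients)
    manifest$truth <- truth_summary
    norm_out <- sub("/+$", "", outdir)
    manifest$files <- as.list(stats::setNames(
      unname(tools::md5sum(files)),
      substring(files, nchar(norm_out) + 2L)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(normal = genome, patients = patients, samples = samples,
                 manifest = manifest, outdir = outdir))
}
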