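#' Simulation parameters for a matched multi-omics cohort
#'
#' Encodes the cohort structure the generator emulates: a breast-brain-
#' metastasis tumor arm (`n_tumor`), non-neoplastic brain and breast reference
#' arms (`n_nbn`, `n_nbr`) and an early-stage primary-tumor arm (`n_primary`),
#' profiled on three platforms (copy-number probes on a dense genomic grid,
#' two-color expression probes collapsed to genes, and a 27K-style beta-value
#' CpG array) at reduced feature counts. Defaults mirror the profiled study
#' arms (15 tumors with copy-number data, 10+10 non-neoplastic references, a
#' scaled-down primary series) and its intrinsic-subtype mix
#' (LumB : Her2ER- : Basal = 12 : 8 : 11).
#'
#' Planted signal (all recorded in the returned ground truth):
#' * copy number: broad (whole-arm) gains/losses and focal
#'   amplifications/deletions with configurable carrier penetrance, plus
#'   homozygous deletions; an explicit `cn_event_spec` data.frame
#'   (`type`, `chrom`, `arm`, `n_probes` with `NA` meaning the whole arm,
#'   `amplitude`, `penetrance`) overrides the automatic placement.
#' * expression: tumor-specific differential genes (`n_deg`, log2 effect
#'   `deg_effect`), brain-vs-breast tissue genes that differ only between the
#'   two references, disjoint per-subtype signature blocks, and a coupling
#'   term adding `cn_coupling` x amplitude to genes inside planted events.
#' * methylation: tumor-specific differentially methylated loci (mostly
#'   hypermethylated, mirroring the published hyper/hypo balance), attenuated
#'   in the primary arm so a metastasis-vs-primary ROC has signal; CpG-island
#'   loci shifted down by `basal_hypomethylation_shift` in basal-like tumors
#'   (the hypomethylator signature); LumB-hypermethylated island loci so the
#'   subtype union exceeds the signature.
#' * drivers: `n_tsg` genes planted as one-copy-deleted + downregulated +
#'   hypermethylated and `n_onco` genes as amplified + upregulated +
#'   hypomethylated in `driver_penetrance` of tumors.
#'
#' Noise: Gaussian on copy-number and expression log ratios; beta-distributed
#' methylation with mean-precision parameterisation `Beta(mu*kappa,
#' (1-mu)*kappa)`, `kappa = beta_concentration` (`Inf` = noise-free, values
#' equal their means).
#'
#' @param ... named overrides of any default (see `formals`/vignette).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(...) {
  p <- list(
    n_tumor = 15L, n_nbn = 10L, n_nbr = 10L, n_primary = 16L,
    n_probes_cn = 4000L, n_probes_expr = 3000L, n_genes = 2000L,
    n_loci_meth = 2000L,
    cn_noise_sd = 0.2, expr_noise_sd = 0.3, beta_concentration = 100,
    subtype_proportions = c(LumB = 12, `Her2ER-` = 8, Basal = 11) / 31,
    basal_hypomethylation_shift = -0.3,
    n_broad_gain = 2L, n_broad_loss = 2L,
    n_focal_amp = 3L, n_focal_del = 3L, n_homozygous_del = 1L,
    focal_n_probes = 20L, event_penetrance = 0.6,
    broad_amplitude = 0.6, focal_amp_amplitude = 1.5,
    focal_del_amplitude = -1.0, homozygous_del_amplitude = -2.5,
    cn_event_spec = NULL, cn_coupling = 0.3,
    n_deg = 100L, deg_effect = 3.0, deg_prop_up = 0.5,
    n_tissue_genes = 50L, tissue_effect = 2.0,
    n_subtype_genes = 40L, subtype_expr_effect = 2.0,
    n_dml = 100L, dml_effect = 0.3, dml_prop_hyper = 0.72,
    primary_attenuation = 0.4,
    n_cihmp = 15L, n_lumb_hyper = 10L,
    n_tsg = 4L, n_onco = 4L, driver_penetrance = 0.8,
    tsg_cn = -1.0, onco_cn = 1.5,
    driver_expr_effect = 3.0, driver_meth_effect = 0.35,
    n_chrom = 4L, chrom_length = 4e7, centromere_fraction = 0.45,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_simulation_params(structure(p, class = "simulation_params"))
}

validate_simulation_params <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  if (p$n_tumor < 2L || p$n_nbn < 2L || p$n_nbr < 2L) {
    stop("each tested group needs at least 2 samples")
  }
  if (abs(sum(p$subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must sum to 1")
  }
  if (!setequal(names(p$subtype_proportions), ANOVA_SUBTYPES)) {
    stop("subtype_proportions must be named over ",
         paste(ANOVA_SUBTYPES, collapse = ", "))
  }
  if (p$cn_noise_sd < 0 || p$expr_noise_sd < 0) stop("noise sd must be >= 0")
  if (p$beta_concentration <= 0) stop("beta_concentration must be positive")
  if (p$basal_hypomethylation_shift > 0) {
    stop("basal_hypomethylation_shift must be <= 0")
  }
  if (p$n_genes < 1L || p$n_probes_cn < p$n_chrom ||
      p$n_probes_expr < p$n_genes || p$n_loci_meth < p$n_genes) {
    stop("infeasible feature counts (need expr probes and CpG loci >= genes)")
  }
  p
}

# deterministic subtype allocation honouring the proportions, then shuffled
allocate_subtypes <- function(n, proportions) {
  counts <- floor(proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(proportions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(proportions), counts))
}

# non-overlapping focal windows allocated left to right within free arms
place_focal_windows <- function(arm_probes, n_events, width, gap = 10L) {
  slots <- list()
  cursors <- vapply(arm_probes, function(idx) idx[1L] + 2L, numeric(1))
  arm_seq <- rep(seq_along(arm_probes), length.out = max(n_events, 0L))
  for (k in seq_len(n_events)) {
    a <- arm_seq[k]
    idx <- arm_probes[[a]]
    from <- cursors[a]
    to <- from + width - 1L
    if (to > idx[length(idx)]) {
      stop("infeasible plant: focal event of ", width,
           " probes does not fit in the remaining arm")
    }
    slots[[k]] <- c(from, to)
    cursors[a] <- to + gap + 1L
  }
  slots
}

#' Simulate a matched copy-number / expression / methylation cohort
#'
#' Generates the three modality matrices, per-platform probe annotation,
#' sample metadata, subtype centroids for the signature genes, and a full
#' record of the planted ground truth. Identical `params` (including the
#' seed) give bit-identical output.
#'
#' @param params a [simulation_params()] object.
#' @return A list of class `bbm_cohort` with elements `cn`, `expr`, `beta`
#'   (each an [omics_matrix()]), `meta`, `ann` (list `cn`/`expr`/`meth`),
#'   `genome` (arm table), `centroids`, `truth`, and `params`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  params <- validate_simulation_params(params)
  set.seed(params$seed)
  arms <- synthetic_genome(params$n_chrom, params$chrom_length,
                           params$centromere_fraction)
  chroms <- unique(arms$chrom)

  ## ---- samples -------------------------------------------------------
  ids <- c(sprintf("BBM%02d", seq_len(params$n_tumor)),
           sprintf("NBn%02d", seq_len(params$n_nbn)),
           sprintf("NBr%02d", seq_len(params$n_nbr)),
           if (params$n_primary > 0) sprintf("PRI%02d", seq_len(params$n_primary)))
  groups <- rep(c("BBM", "NBn", "NBr", "PRIMARY"),
                c(params$n_tumor, params$n_nbn, params$n_nbr, params$n_primary))
  subtype <- rep("unknown", length(ids))
  subtype[groups == "BBM"] <-
    allocate_subtypes(params$n_tumor, params$subtype_proportions)
  meta <- validate_metadata(data.frame(
    sample_id = ids, group = groups, subtype = subtype,
    stringsAsFactors = FALSE))
  tumors <- ids[groups == "BBM"]
  nsamp <- length(ids)

  ## ---- genomic grid --------------------------------------------------
  per_chr_cn <- rep(params$n_probes_cn %/% length(chroms), length(chroms))
  per_chr_cn[seq_len(params$n_probes_cn %% length(chroms))] <-
    per_chr_cn[seq_len(params$n_probes_cn %% length(chroms))] + 1L
  cn_chrom <- rep(chroms, per_chr_cn)
  cn_pos <- unlist(lapply(seq_along(chroms), function(k) {
    sp <- params$chrom_length / per_chr_cn[k]
    as.integer(floor((seq_len(per_chr_cn[k]) - 0.5) * sp))
  }))
  cn_ids <- sprintf("cnp%06d", seq_along(cn_pos))

  per_chr_gene <- rep(params$n_genes %/% length(chroms), length(chroms))
  per_chr_gene[seq_len(params$n_genes %% length(chroms))] <-
    per_chr_gene[seq_len(params$n_genes %% length(chroms))] + 1L
  gene_chrom <- rep(chroms, per_chr_gene)
  gene_start <- unlist(lapply(seq_along(chroms), function(k) {
    sp <- params$chrom_length / per_chr_gene[k]
    as.integer(floor((seq_len(per_chr_gene[k]) - 0.5) * sp))
  }))
  genes <- data.frame(
    gene_symbol = sprintf("G%04d", seq_len(params$n_genes)),
    chrom = gene_chrom, start = gene_start,
    end = gene_start + 10000L, stringsAsFactors = FALSE)

  ## ---- copy-number events --------------------------------------------
  arm_probe_idx <- lapply(seq_len(nrow(arms)), function(a) {
    which(cn_chrom == arms$chrom[a] & cn_pos >= arms$start[a] &
          cn_pos < arms$end[a])
  })
  events <- list()
  add_event <- function(type, probes, amplitude, carriers, gene = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      event_id = sprintf("ev%02d", length(events) + 1L), type = type,
      chrom = cn_chrom[probes[1L]],
      start = cn_pos[probes[1L]], end = cn_pos[probes[length(probes)]] + 1L,
      start_probe = probes[1L], end_probe = probes[length(probes)],
      amplitude = amplitude, gene = gene,
      carriers = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE)
  }
  pick_carriers <- function(penetrance) {
    n <- max(1L, round(penetrance * length(tumors)))
    if (n >= length(tumors)) tumors else sample(tumors, n)
  }

  if (!is.null(params$cn_event_spec)) {
    spec <- params$cn_event_spec
    for (r in seq_len(nrow(spec))) {
      a <- which(arms$chrom == spec$chrom[r] & arms$arm == spec$arm[r])
      if (!length(a)) stop("unknown arm in cn_event_spec")
      idx <- arm_probe_idx[[a]]
      w <- spec$n_probes[r]
      if (is.na(w)) {
        probes <- idx
      } else {
        if (w + 2L > length(idx)) {
          stop("infeasible plant: event larger than arm")
        }
        probes <- idx[1L + seq_len(w)]  # leave a one-probe flank at the arm edge
      }
      add_event(spec$type[r], probes, spec$amplitude[r],
                pick_carriers(spec$penetrance[r]))
    }
  } else {
    n_broad <- params$n_broad_gain + params$n_broad_loss
    if (n_broad > nrow(arms)) stop("infeasible plant: more broad events than arms")
    broad_arms <- sample(nrow(arms), n_broad)
    for (k in seq_len(n_broad)) {
      gain <- k <= params$n_broad_gain
      add_event(if (gain) "broad_gain" else "broad_loss",
                arm_probe_idx[[broad_arms[k]]],
                if (gain) params$broad_amplitude else -params$broad_amplitude,
                pick_carriers(params$event_penetrance))
    }
    free_arms <- arm_probe_idx[setdiff(seq_len(nrow(arms)), broad_arms)]
    if (!length(free_arms)) free_arms <- arm_probe_idx
    n_focal <- params$n_focal_amp + params$n_focal_del +
      params$n_homozygous_del + params$n_tsg + params$n_onco
    slots <- place_focal_windows(free_arms, n_focal, params$focal_n_probes)
    types <- c(rep("focal_amp", params$n_focal_amp),
               rep("focal_del", params$n_focal_del),
               rep("homozygous_del", params$n_homozygous_del),
               rep("tsg", params$n_tsg), rep("onco", params$n_onco))
    amps <- c(rep(params$focal_amp_amplitude, params$n_focal_amp),
              rep(params$focal_del_amplitude, params$n_focal_del),
              rep(params$homozygous_del_amplitude, params$n_homozygous_del),
              rep(params$tsg_cn, params$n_tsg),
              rep(params$onco_cn, params$n_onco))
    for (k in seq_len(n_focal)) {
      probes <- slots[[k]][1L]:slots[[k]][2L]
      pen <- if (types[k] %in% c("tsg", "onco")) params$driver_penetrance
             else params$event_penetrance
      # the gene anchoring a driver / homozygous-deletion event: the one whose
      # interval overlaps the event midpoint region
      gene <- NA_character_
      if (types[k] %in% c("tsg", "onco", "homozygous_del")) {
        mid <- cn_pos[probes[ceiling(length(probes) / 2)]]
        cand <- which(genes$chrom == cn_chrom[probes[1L]] &
                      genes$start <= mid & genes$end > mid)
        if (!length(cand)) {
          cand <- which(genes$chrom == cn_chrom[probes[1L]] &
                        genes$start >= cn_pos[probes[1L]] &
                        genes$end <= cn_pos[probes[length(probes)]] + 1L)
        }
        if (!length(cand)) stop("infeasible plant: no gene under driver event")
        gene <- genes$gene_symbol[cand[1L]]
      }
      add_event(types[k], probes, amps[k], pick_carriers(pen), gene)
    }
  }
  cn_events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0), type = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               start_probe = integer(0), end_probe = integer(0),
               amplitude = numeric(0), gene = character(0),
               carriers = character(0), stringsAsFactors = FALSE)

  ## ---- disjoint gene pools for planted signal ------------------------
  # drawn after event placement so planted expression/methylation genes
  # never sit inside a planted copy-number event (which would confound the
  # coupling term and the driver effects)
  in_event <- rep(FALSE, params$n_genes)
  for (r in seq_len(nrow(cn_events))) {
    in_event <- in_event | (genes$chrom == cn_events$chrom[r] &
                              genes$end > cn_events$start[r] &
                              genes$start < cn_events$end[r])
  }
  pool <- sample(which(!in_event))
  take <- local({
    used <- 0L
    function(n) {
      if (n == 0L) return(integer(0))
      if (used + n > length(pool)) stop("not enough genes for planted signal")
      out <- pool[used + seq_len(n)]
      used <<- used + n
      out
    }
  })
  deg_idx <- take(params$n_deg)
  tissue_idx <- take(params$n_tissue_genes)
  subtype_idx <- lapply(setNames(ANOVA_SUBTYPES, ANOVA_SUBTYPES),
                        function(s) take(params$n_subtype_genes))
  dml_idx <- take(params$n_dml)
  cihmp_idx <- take(params$n_cihmp)
  lumb_idx <- take(params$n_lumb_hyper)

  ## ---- copy-number matrix --------------------------------------------
  cn <- matrix(0, length(cn_ids), nsamp, dimnames = list(cn_ids, ids))
  for (r in seq_len(nrow(cn_events))) {
    carr <- strsplit(cn_events$carriers[r], ",", fixed = TRUE)[[1L]]
    rows <- cn_events$start_probe[r]:cn_events$end_probe[r]
    cn[rows, carr] <- cn[rows, carr] + cn_events$amplitude[r]
  }
  if (params$cn_noise_sd > 0) {
    cn <- cn + matrix(rnorm(length(cn), 0, params$cn_noise_sd), nrow(cn))
  }

  ## ---- expression (gene level, replicated to probes) -----------------
  baseline <- rnorm(params$n_genes, 0, 0.3)
  gexpr <- matrix(rep(baseline, nsamp), params$n_genes, nsamp,
                  dimnames = list(genes$gene_symbol, ids))
  deg_dir <- rep(c(1, -1), length.out = params$n_deg)
  if (params$n_deg > 0) {
    up <- runif(params$n_deg) < params$deg_prop_up
    deg_dir <- ifelse(up, 1, -1)
    gexpr[deg_idx, tumors] <- gexpr[deg_idx, tumors] +
      deg_dir * params$deg_effect
  }
  if (params$n_tissue_genes > 0) {
    tis_dir <- rep(c(1, -1), length.out = params$n_tissue_genes)
    nbn_ids <- ids[groups == "NBn"]
    gexpr[tissue_idx, nbn_ids] <- gexpr[tissue_idx, nbn_ids] +
      tis_dir * params$tissue_effect
  }
  for (s in ANOVA_SUBTYPES) {
    members <- meta$sample_id[meta$group == "BBM" & meta$subtype == s]
    if (length(members) && length(subtype_idx[[s]])) {
      gexpr[subtype_idx[[s]], members] <- gexpr[subtype_idx[[s]], members] +
        params$subtype_expr_effect
    }
  }
  # copy-number coupling: genes inside planted events move with the event
  for (r in seq_len(nrow(cn_events))) {
    carr <- strsplit(cn_events$carriers[r], ",", fixed = TRUE)[[1L]]
    gsel <- genes$chrom == cn_events$chrom[r] &
      genes$end > cn_events$start[r] & genes$start < cn_events$end[r]
    if (any(gsel)) {
      gexpr[gsel, carr] <- gexpr[gsel, carr] +
        params$cn_coupling * cn_events$amplitude[r]
    }
  }
  # explicit driver expression effects
  drv <- cn_events[cn_events$type %in% c("tsg", "onco", "homozygous_del"), ,
                   drop = FALSE]
  for (r in seq_len(nrow(drv))) {
    carr <- strsplit(drv$carriers[r], ",", fixed = TRUE)[[1L]]
    eff <- if (drv$type[r] == "onco") params$driver_expr_effect else
      -params$driver_expr_effect
    gexpr[drv$gene[r], carr] <- gexpr[drv$gene[r], carr] + eff
  }
  if (params$expr_noise_sd > 0) {
    gexpr <- gexpr + matrix(rnorm(length(gexpr), 0, params$expr_noise_sd),
                            nrow(gexpr))
  }
  # probe-level expression: every probe of a gene reports the gene value
  probe_gene <- rep(seq_len(params$n_genes),
                    length.out = params$n_probes_expr)
  probe_gene <- sort(probe_gene)
  expr_ids <- sprintf("ep%05d", seq_len(params$n_probes_expr))
  expr <- gexpr[probe_gene, , drop = FALSE]
  rownames(expr) <- expr_ids

  ## ---- methylation ----------------------------------------------------
  locus_gene <- rep(seq_len(params$n_genes), length.out = params$n_loci_meth)
  locus_ids <- sprintf("cg%05d", seq_len(params$n_loci_meth))
  island <- runif(params$n_loci_meth) < 0.4
  mu0 <- ifelse(island, 0.10, 0.55)

  loci_of <- function(gidx) match(gidx, locus_gene)  # first locus of each gene
  dml_loci <- loci_of(dml_idx)
  cihmp_loci <- loci_of(cihmp_idx)
  lumb_loci <- loci_of(lumb_idx)
  drv_loci <- if (nrow(drv)) loci_of(match(drv$gene, genes$gene_symbol)) else integer(0)

  dml_hyper <- runif(params$n_dml) < params$dml_prop_hyper
  if (params$n_dml > 0) {
    island[dml_loci] <- runif(params$n_dml) <
      ifelse(dml_hyper, 0.95, 0.2)  # hyper-DML sit in islands, hypo rarely
    mu0[dml_loci] <- ifelse(dml_hyper, 0.15, 0.65)
  }
  island[cihmp_loci] <- TRUE
  mu0[cihmp_loci] <- 0.60
  island[lumb_loci] <- TRUE
  mu0[lumb_loci] <- 0.30
  if (length(drv_loci)) {
    island[drv_loci] <- TRUE
    mu0[drv_loci] <- ifelse(drv$type == "onco", 0.60, 0.20)
  }

  mu <- matrix(rep(mu0, nsamp), params$n_loci_meth, nsamp,
               dimnames = list(locus_ids, ids))
  # small brain/breast tissue offset at tumor-specific DML loci
  if (params$n_dml > 0) {
    mu[dml_loci, ids[groups == "NBn"]] <-
      mu[dml_loci, ids[groups == "NBn"]] + 0.05
    eff <- ifelse(dml_hyper, params$dml_effect, -params$dml_effect)
    mu[dml_loci, tumors] <- mu[dml_loci, tumors] + eff
    prim <- ids[groups == "PRIMARY"]
    if (length(prim)) {
      mu[dml_loci, prim] <- mu[dml_loci, prim] +
        params$primary_attenuation * eff
    }
  }
  basal <- meta$sample_id[meta$group == "BBM" & meta$subtype == "Basal"]
  if (length(basal) && length(cihmp_loci)) {
    mu[cihmp_loci, basal] <- mu[cihmp_loci, basal] +
      params$basal_hypomethylation_shift
  }
  lumb <- meta$sample_id[meta$group == "BBM" & meta$subtype == "LumB"]
  if (length(lumb) && length(lumb_loci)) {
    mu[lumb_loci, lumb] <- mu[lumb_loci, lumb] + 0.3
  }
  for (r in seq_len(nrow(drv))) {
    carr <- strsplit(drv$carriers[r], ",", fixed = TRUE)[[1L]]
    shift <- if (drv$type[r] == "onco") -params$driver_meth_effect else
      params$driver_meth_effect
    mu[drv_loci[r], carr] <- mu[drv_loci[r], carr] + shift
  }
  mu <- pmin(pmax(mu, 0.02), 0.98)
  if (is.finite(params$beta_concentration)) {
    k <- params$beta_concentration
    beta <- matrix(rbeta(length(mu), mu * k, (1 - mu) * k), nrow(mu),
                   dimnames = dimnames(mu))
  } else {
    beta <- mu
  }

  ## ---- annotation ----------------------------------------------------
  cn_gene <- rep("", length(cn_ids))
  for (ch in chroms) {
    gsel <- which(genes$chrom == ch)
    psel <- which(cn_chrom == ch)
    hit <- findInterval(cn_pos[psel], genes$start[gsel])
    ok <- hit >= 1L & cn_pos[psel] < genes$end[gsel][pmax(hit, 1L)]
    cn_gene[psel[ok]] <- genes$gene_symbol[gsel[hit[ok]]]
  }
  ann_cn <- data.frame(probe_id = cn_ids, gene_symbol = cn_gene,
                       chrom = cn_chrom, start = cn_pos, end = cn_pos + 1L,
                       cpg_island = NA, stringsAsFactors = FALSE)
  ann_expr <- data.frame(
    probe_id = expr_ids, gene_symbol = genes$gene_symbol[probe_gene],
    chrom = genes$chrom[probe_gene],
    start = genes$start[probe_gene] + 100L * (seq_along(probe_gene) %% 5L),
    end = genes$start[probe_gene] + 100L * (seq_along(probe_gene) %% 5L) + 60L,
    cpg_island = NA, stringsAsFactors = FALSE)
  ann_meth <- data.frame(
    probe_id = locus_ids, gene_symbol = genes$gene_symbol[locus_gene],
    chrom = genes$chrom[locus_gene], start = genes$start[locus_gene],
    end = genes$start[locus_gene] + 2L, cpg_island = island,
    stringsAsFactors = FALSE)

  ## ---- centroids over the signature genes ----------------------------
  sig_genes <- sort(unlist(subtype_idx))
  centroids <- NULL
  if (length(sig_genes)) {
    centroids <- vapply(ANOVA_SUBTYPES, function(s) {
      baseline[sig_genes] +
        params$subtype_expr_effect * (sig_genes %in% subtype_idx[[s]])
    }, numeric(length(sig_genes)))
    rownames(centroids) <- genes$gene_symbol[sig_genes]
  }

  ## ---- ground truth ---------------------------------------------------
  truth <- list(
    cn_events = cn_events,
    deg = if (params$n_deg > 0) data.frame(
      gene = genes$gene_symbol[deg_idx],
      direction = ifelse(deg_dir > 0, "up", "down"),
      effect = deg_dir * params$deg_effect, stringsAsFactors = FALSE)
      else data.frame(gene = character(0), direction = character(0),
                      effect = numeric(0)),
    tissue_genes = genes$gene_symbol[tissue_idx],
    subtype_genes = if (params$n_subtype_genes > 0) data.frame(
      gene = genes$gene_symbol[unlist(subtype_idx)],
      subtype = rep(ANOVA_SUBTYPES, each = params$n_subtype_genes),
      stringsAsFactors = FALSE)
      else data.frame(gene = character(0), subtype = character(0)),
    dml = if (params$n_dml > 0) data.frame(
      locus_id = locus_ids[dml_loci],
      gene = genes$gene_symbol[dml_idx],
      direction = ifelse(dml_hyper, "hyper", "hypo"),
      effect = ifelse(dml_hyper, params$dml_effect, -params$dml_effect),
      cpg_island = island[dml_loci], stringsAsFactors = FALSE)
      else data.frame(locus_id = character(0), gene = character(0),
                      direction = character(0), effect = numeric(0),
                      cpg_island = logical(0)),
    cihmp_loci = locus_ids[cihmp_loci],
    lumb_hyper_loci = locus_ids[lumb_loci],
    roc_loci = locus_ids[dml_loci],
    drivers = if (nrow(drv)) data.frame(
      gene = drv$gene,
      role = c(tsg = "tsg", onco = "onco",
               homozygous_del = "homozygous_del")[drv$type],
      locus_id = locus_ids[drv_loci],
      cn_amplitude = drv$amplitude, carriers = drv$carriers,
      stringsAsFactors = FALSE)
      else data.frame(gene = character(0), role = character(0),
                      locus_id = character(0), cn_amplitude = numeric(0),
                      carriers = character(0)),
    subtype = setNames(meta$subtype, meta$sample_id)
  )

  structure(list(
    cn = omics_matrix(cn, "cn_log2"),
    expr = omics_matrix(expr, "expr_log2"),
    beta = omics_matrix(beta, "beta"),
    meta = meta,
    ann = list(cn = validate_annotation(ann_cn),
               expr = validate_annotation(ann_expr),
               meth = validate_annotation(ann_meth, methylation = TRUE)),
    genome = arms,
    genes = genes,
    centroids = centroids,
    truth = truth,
    params = params
  ), class = "bbm_cohort")
}

#' Simulate a cohort with no planted signal
#'
#' Same machinery and group structure as [simulate_cohort()] with every
#' planted effect zeroed: pure noise around flat baselines, empty ground
#' truth. Used for null calibration of the differential callers and the
#' recurrence permutation test.
#'
#' @param params a [simulation_params()] object.
#' @return A `bbm_cohort` whose `truth` component is empty.
#' @export
simulate_null_cohort <- function(params = simulation_params()) {
  params <- validate_simulation_params(params)
  zero <- list(n_broad_gain = 0L, n_broad_loss = 0L, n_focal_amp = 0L,
               n_focal_del = 0L, n_homozygous_del = 0L, n_tsg = 0L,
               n_onco = 0L, n_deg = 0L, n_tissue_genes = 0L,
               n_subtype_genes = 0L, n_dml = 0L, n_cihmp = 0L,
               n_lumb_hyper = 0L, cn_event_spec = NULL,
               basal_hypomethylation_shift = 0)
  p <- unclass(params)
  p[names(zero)] <- zero
  simulate_cohort(structure(p, class = "simulation_params"))
}

#' @export
print.bbm_cohort <- function(x, ...) {
  cat(sprintf(
    "bbm_cohort: %d samples (%s)\n  cn %d probes | expr %d probes / %d genes | beta %d loci\n",
    nrow(x$meta),
    paste(sprintf("%s=%d", names(table(x$meta$group)), table(x$meta$group)),
          collapse = ", "),
    nrow(x$cn), nrow(x$expr), nrow(x$genes), nrow(x$beta)))
  invisible(x)
}
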