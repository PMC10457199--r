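# End-to-end orchestration: simulate -> meta -> signals -> coloc -> mr
# -> mediator prioritization, from one config, with per-stage outputs
# and manifests. All randomness derives from the config seed, so a rerun
# with the same config reproduces byte-identical outputs.

#' Default pipeline configuration
#'
#' Collects every stage threshold (at its standard default) and the
#' synthetic study design: three proteins (two cis-regulated, one with a
#' trans signal carrying a planted mediator gene), a whole-blood-scale
#' eQTL dataset per relevant gene, and one case-control disease GWAS
#' causally downstream of the first protein.
#'
#' @param seed Integer master seed.
#' @param n_cohorts,cohort_ns,n_blocks,block_size,rho,maf_range Passed
#'   to [sim_config()].
#' @param theta Causal effect of protein P1 on disease log-odds
#'   (default 0.3).
#' @param overrides Named list of top-level overrides applied last
#'   (e.g. `list(min_studies = 999)`).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cohorts = 11, cohort_ns = NULL,
                            n_blocks = 4, block_size = 50, rho = 0.8,
                            maf_range = c(0.05, 0.5), theta = 0.3,
                            overrides = NULL) {
  if (is.null(cohort_ns)) cohort_ns <- default_cohort_ns(n_cohorts)
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_cohorts = n_cohorts, cohort_ns = cohort_ns,
               n_blocks = n_blocks, block_size = block_size, rho = rho,
               maf_range = maf_range, theta = theta,
               eqtl_n = 31684, disease_cases = 10000,
               disease_controls = 30000),
    qc = list(maf_min = 0.001, hwe_min = 1e-6, info_min = 0.3),
    meta = list(p_sig = 5e-10, i2_max = 30, min_studies = 3,
                min_n = 3500, min_consistent = 3),
    signals = list(flank = 1e6, cis_window = 1e6, p_enter = 5e-10,
                   maf_floor = 0.01, collinearity = 0.9, prune_r2 = 0.1),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, pp4_rule = 0.8,
                 p_cutoff = 5e-8),
    mr = list(p_thresh = 5e-8, clump_r2 = 0.1, freq_diff_max = 0.4,
              min_instruments = 3, p_heidi = 0.05, q_max = 0.01,
              locus_p_max = 1e-4, r2_min = 0.8),
    progem = list(window = 5e5, eqtl_r2 = 0.8)
  )
  for (nm in names(overrides)) {
    hit <- FALSE
    for (sec in names(cfg)) {
      if (is.list(cfg[[sec]]) && nm %in% names(cfg[[sec]])) {
        cfg[[sec]][[nm]] <- overrides[[nm]]
        hit <- TRUE
      }
    }
    if (!hit) cfg[[nm]] <- overrides[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly. The round trip
#'   is lossless.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (sec in names(cfg)) {
    if (is.list(base[[sec]]) && is.list(cfg[[sec]])) {
      for (nm in names(cfg[[sec]])) base[[sec]][[nm]] <- cfg[[sec]][[nm]]
    } else base[[sec]] <- cfg[[sec]]
  }
  base$seed <- as.integer(base$seed)
  base
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# The bundled synthetic study design (positions on the panel built from
# the config): returns gene annotation + truth tables.
.study_design <- function(panel) {
  v <- panel$variants
  pick <- function(block, k) v$id[v$block == block][k]
  genes <- data.frame(
    gene = c("G1", "G2", "G3", paste0("L", 1:8)),
    chrom = c("1", "1", "2",
              rep("1", 8)),
    tss = c(120000L, 10100000L, 5000000L,
            # local candidates around the trans locus (block 3 start 2e7)
            as.integer(2e7 + c(30000, 60000, 90000, 130000, 180000,
                               240000, 320000, 420000))),
    terms = c(
      "T1;T2;T3;T4;T5;T6;T7;T8",                 # G1
      "T9;T10;T11;T12",                          # G2
      "T1;T2;T3;T20;T21;T22;T23;T24",            # G3 (trans target)
      "T1;T2;T3;T20;T21;T25",                    # L1: planted mediator
      "T30;T31", "T32;T33", "T34;T35", "T36;T37",
      "T38;T39", "T40;T41", "T42;T43"),
    partners = c("", "", "L1",
                 "G3", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
  truth <- rbind(
    truth_table("P1", pick(1, c(15, 40)), c(0.35, 0.25),
                shared_with = c("E_G1", ""), tau = 0),
    truth_table("P2", pick(2, 25), 0.30, tau = 0.05),
    truth_table("P3", pick(3, 10), 0.30, shared_with = "E_L1", tau = 0)
  )
  eqtl_truth <- rbind(
    truth_table("E_G1", pick(1, 15), 0.20),
    truth_table("E_L1", pick(3, 10), 0.25)
  )
  # proteins are encoded by: P1 -> G1 (cis, block 1), P2 -> G2 (cis,
  # block 2), P3 -> G3 (chrom 2; its block-3 signal is trans)
  proteins <- data.frame(
    protein = c("P1", "P2", "P3"),
    gene = c("G1", "G2", "G3"),
    stringsAsFactors = FALSE
  )
  list(genes = genes, truth = truth, eqtl_truth = eqtl_truth,
       proteins = proteins)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.manifest <- function(out_dir, stage, params, counts, seed, inputs = NULL) {
  mf <- list(stage = stage, seed = seed, params = params, counts = counts)
  if (!is.null(inputs))
    mf$input_md5 <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(mf, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline on the bundled synthetic design
#'
#' Executes simulate -> QC/meta -> signal definition -> eQTL/pQTL
#' colocalization -> cis-MR on the disease outcome -> mediator
#' prioritization at the trans locus, writing per-stage TSVs and JSON
#' manifests (threshold values, seed, record counts) under `out_dir`.
#' Identical configs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a run report list with per-stage summaries and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- sim_config(n_cohorts = config$sim$n_cohorts,
                   cohort_ns = config$sim$cohort_ns,
                   n_blocks = config$sim$n_blocks,
                   block_size = config$sim$block_size,
                   rho = config$sim$rho,
                   maf_range = config$sim$maf_range,
                   seed = config$seed)
  panel <- simulate_ld_panel(sc)
  design <- .study_design(panel)

  ## --- simulate ------------------------------------------------------
  protein_ids <- design$proteins$protein
  cohorts <- lapply(seq_along(protein_ids), function(i)
    simulate_protein_gwas(panel, design$truth, sc,
                          trait = protein_ids[i],
                          seed_offset = 10000L * i))
  names(cohorts) <- protein_ids
  eq_cfg <- sim_config(n_cohorts = 1, cohort_ns = config$sim$eqtl_n,
                       n_blocks = sc$n_blocks, block_size = sc$block_size,
                       rho = sc$rho, maf_range = sc$maf_range,
                       seed = config$seed)
  eqtl <- lapply(seq_len(nrow(design$eqtl_truth)), function(i)
    simulate_protein_gwas(panel, design$eqtl_truth, eq_cfg,
                          trait = design$eqtl_truth$trait[i],
                          seed_offset = 90000L + 10000L * i)[[1]])
  names(eqtl) <- design$eqtl_truth$trait
  disease <- simulate_disease_gwas(
    panel, design$truth[design$truth$trait == "P1", ],
    theta = config$sim$theta, confounder_mode = "none", config = sc,
    n_cases = config$sim$disease_cases,
    n_controls = config$sim$disease_controls)
  .write_tsv(panel$variants, file.path(out_dir, "panel_variants.tsv"))
  write_sumstats(disease, file.path(out_dir, "disease_gwas.tsv"))
  .write_tsv(design$genes, file.path(out_dir, "gene_annotation.tsv"))
  .manifest(out_dir, "simulate",
            params = config$sim,
            counts = list(n_variants = nrow(panel$variants),
                          n_proteins = length(protein_ids),
                          n_eqtl_sets = length(eqtl)),
            seed = config$seed)

  ## --- meta ----------------------------------------------------------
  meta <- lapply(protein_ids, function(p) {
    filtered <- lapply(cohorts[[p]], cohort_qc,
                       maf_min = config$qc$maf_min,
                       hwe_min = config$qc$hwe_min,
                       info_min = config$qc$info_min)
    m <- meta_analyse(filtered)
    apply_meta_filters(m, p_sig = config$meta$p_sig,
                       i2_max = config$meta$i2_max,
                       min_studies = config$meta$min_studies,
                       min_n = config$meta$min_n,
                       min_consistent = config$meta$min_consistent)
  })
  names(meta) <- protein_ids
  for (p in protein_ids)
    .write_tsv(meta[[p]], file.path(out_dir, paste0("meta_", p, ".tsv")))
  n_sig <- vapply(meta, function(m)
    sum(m$verdict == "significant"), integer(1))
  .manifest(out_dir, "meta", params = c(config$qc, config$meta),
            counts = list(n_significant = as.list(n_sig),
                          lambda = lapply(meta, function(m)
                            genomic_lambda(z = m$z_meta))),
            seed = config$seed)

  ## --- signals -------------------------------------------------------
  regions <- NULL
  conditional <- list()
  for (p in protein_ids) {
    m <- meta[[p]]
    sig <- m[m$verdict == "significant", , drop = FALSE]
    reg <- define_regions(sig, flank = config$signals$flank)
    if (!nrow(reg)) next
    gene <- design$proteins$gene[design$proteins$protein == p]
    gi <- match(gene, design$genes$gene)
    reg$protein <- p
    reg$label <- vapply(seq_len(nrow(reg)), function(i)
      classify_cis_trans(reg[i, ], design$genes$tss[gi],
                         design$genes$chrom[gi],
                         cis_window = config$signals$cis_window), "")
    for (i in seq_len(nrow(reg))) {
      in_reg <- m$chrom == reg$chrom[i] & m$pos >= reg$start[i] &
        m$pos <= reg$end[i] & m$verdict == "significant"
      st <- m[in_reg, , drop = FALSE]
      st$beta <- st$beta_meta; st$se <- st$se_meta; st$n <- st$n_total
      cs <- conditional_stepwise(st, panel$ld,
                                 p_enter = config$signals$p_enter,
                                 maf_floor = config$signals$maf_floor,
                                 collinearity = config$signals$collinearity,
                                 sentinel = reg$sentinel_id[i])
      cs <- prune_signals(
        cbind(cs, mlog10p = cs$mlog10p_joint), panel$ld,
        r2_max = config$signals$prune_r2, forced = reg$sentinel_id[i])
      conditional[[paste(p, reg$sentinel_id[i])]] <- cs
      reg$n_conditional[i] <- nrow(cs)
    }
    sent <- m[match(reg$sentinel_id, m$id), ]
    reg$pve_contribution <- compute_pve(sent$beta_meta, sent$se_meta,
                                        sent$n_total)$terms
    regions <- rbind(regions, reg)
  }
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_variants = integer(),
                          sentinel_id = character(),
                          sentinel_pos = numeric(),
                          sentinel_mlog10p = numeric(),
                          protein = character(), label = character(),
                          n_conditional = integer(),
                          pve_contribution = numeric(),
                          stringsAsFactors = FALSE)
  .write_tsv(regions, file.path(out_dir, "regions.tsv"))
  # BED export of regions (0-based half-open)
  .write_tsv(data.frame(chrom = regions$chrom, start = regions$start - 1,
                        end = regions$end, name = paste(regions$protein,
                                                        regions$sentinel_id)),
             file.path(out_dir, "regions.bed"))
  cond_tab <- do.call(rbind, lapply(names(conditional), function(k)
    cbind(locus = k, conditional[[k]][
      , c("id", "beta_joint", "se_joint", "mlog10p_joint")])))
  if (is.null(cond_tab))
    cond_tab <- data.frame(locus = character(), id = character(),
                           beta_joint = numeric(), se_joint = numeric(),
                           mlog10p_joint = numeric())
  .write_tsv(cond_tab, file.path(out_dir, "conditional_signals.tsv"))
  .manifest(out_dir, "signals", params = config$signals,
            counts = list(n_regions = if (is.null(regions)) 0L else nrow(regions),
                          n_conditional = sum(vapply(conditional, nrow,
                                                     integer(1)))),
            seed = config$seed)

  ## --- coloc (cis-pQTL vs cognate cis-eQTL) --------------------------
  coloc_rows <- NULL
  cis_reg <- regions[regions$label == "cis", , drop = FALSE]
  for (i in seq_len(nrow(cis_reg))) {
    p <- cis_reg$protein[i]
    gene <- design$proteins$gene[design$proteins$protein == p]
    eq_name <- paste0("E_", gene)
    if (!eq_name %in% names(eqtl)) next
    m <- meta[[p]]
    in_reg <- m$chrom == cis_reg$chrom[i] & m$pos >= cis_reg$start[i] &
      m$pos <= cis_reg$end[i]
    pq <- m[in_reg, , drop = FALSE]
    pq$beta <- pq$beta_meta; pq$se <- pq$se_meta; pq$n <- pq$n_total
    eq <- eqtl[[eq_name]]
    eq <- eq[eq$id %in% pq$id, , drop = FALSE]
    pw <- pwcoco(pq, eq, panel$ld, p_cutoff = config$coloc$p_cutoff,
                 collinearity = config$signals$collinearity,
                 p1 = config$coloc$p1, p2 = config$coloc$p2,
                 p12 = config$coloc$p12, pp4_rule = config$coloc$pp4_rule)
    pp <- pw$results$unconditioned$pp
    coloc_rows <- rbind(coloc_rows, data.frame(
      protein = p, eqtl = eq_name, t(pp), max_pp4 = pw$max_pp4,
      colocalized = pw$colocalized, stringsAsFactors = FALSE))
  }
  if (is.null(coloc_rows))
    coloc_rows <- data.frame(protein = character(), eqtl = character(),
                             PP0 = numeric(), PP1 = numeric(),
                             PP2 = numeric(), PP3 = numeric(),
                             PP4 = numeric(), max_pp4 = numeric(),
                             colocalized = logical())
  .write_tsv(coloc_rows, file.path(out_dir, "coloc.tsv"))
  .manifest(out_dir, "coloc", params = config$coloc,
            counts = list(n_pairs = if (is.null(coloc_rows)) 0L
                          else nrow(coloc_rows)),
            seed = config$seed)

  ## --- MR ------------------------------------------------------------
  mr_rows <- NULL
  for (p in protein_ids) {
    gene <- design$proteins$gene[design$proteins$protein == p]
    gi <- match(gene, design$genes$gene)
    m <- meta[[p]]
    in_cis <- m$chrom == design$genes$chrom[gi] &
      abs(m$pos - design$genes$tss[gi]) <= 1e6
    expo <- m[in_cis & m$verdict %in% c("significant", "not_significant"),
              , drop = FALSE]
    row <- if (!nrow(expo)) {
      data.frame(status = "insufficient", b_xy = NA_real_,
                 se_xy = NA_real_, p_xy = NA_real_, or_ = NA_real_,
                 or_lo = NA_real_, or_hi = NA_real_,
                 n_instruments_selected = 0L, n_instruments_used = 0L,
                 heidi_removed = "", sentinel_id = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      expo$beta <- expo$beta_meta; expo$se <- expo$se_meta
      expo$n <- expo$n_total; expo$p <- expo$p_meta
      mr_protein_disease(expo, disease, panel$ld,
                         p_thresh = config$mr$p_thresh,
                         clump_r2 = config$mr$clump_r2,
                         freq_diff_max = config$mr$freq_diff_max,
                         min_instruments = config$mr$min_instruments,
                         p_heidi = config$mr$p_heidi)
    }
    row$protein <- p
    row$disease <- "D1"
    # locus audit values for the robustness filters
    if (!is.na(row$sentinel_id)) {
      si <- match(row$sentinel_id, disease$id)
      loc <- disease[disease$chrom == m$chrom[1] &
                       abs(disease$pos - disease$pos[si]) <= 1e6, ]
      row$disease_min_p <- 10^(-max(loc$mlog10p))
      best <- loc$id[which.max(loc$mlog10p)]
      row$r2_sentinel_disease <-
        panel$ld$r[match(row$sentinel_id, panel$ld$variants$id),
                   match(best, panel$ld$variants$id)]^2
      expo$beta <- expo$beta_meta; expo$se <- expo$se_meta
      dz <- disease[disease$id %in% expo$id, , drop = FALSE]
      pw <- tryCatch(
        pwcoco(expo, dz, panel$ld, p_cutoff = config$coloc$p_cutoff,
               p1 = config$coloc$p1, p2 = config$coloc$p2,
               p12 = config$coloc$p12, type2 = "case_control"),
        error = function(e) NULL)
      row$max_pp4 <- if (is.null(pw)) NA_real_ else pw$max_pp4
    } else {
      row$disease_min_p <- NA_real_
      row$r2_sentinel_disease <- NA_real_
      row$max_pp4 <- NA_real_
    }
    mr_rows <- rbind(mr_rows, row)
  }
  mr_rows <- fdr_and_robustness(mr_rows, q_max = config$mr$q_max,
                                locus_p_max = config$mr$locus_p_max,
                                r2_min = config$mr$r2_min,
                                pp4_min = config$coloc$pp4_rule)
  .write_tsv(mr_rows, file.path(out_dir, "mr_results.tsv"))
  .manifest(out_dir, "mr", params = config$mr,
            counts = list(n_models = nrow(mr_rows),
                          n_ok = sum(mr_rows$status == "ok")),
            seed = config$seed)

  ## --- mediator prioritization at the trans locus --------------------
  progem_tab <- NULL
  trans_reg <- regions[regions$label == "trans", , drop = FALSE]
  for (i in seq_len(nrow(trans_reg))) {
    p <- trans_reg$protein[i]
    gene <- design$proteins$gene[design$proteins$protein == p]
    rep_i <- prioritize_mediators(
      trans_reg$chrom[i], trans_reg$sentinel_pos[i],
      trans_reg$sentinel_id[i], gene, design$genes,
      eqtl = list(L1 = eqtl[["E_L1"]]), ld = panel$ld,
      window = config$progem$window, eqtl_r2 = config$progem$eqtl_r2)
    if (nrow(rep_i)) {
      rep_i$protein <- p
      rep_i$sentinel <- trans_reg$sentinel_id[i]
      progem_tab <- rbind(progem_tab, rep_i)
    }
  }
  if (is.null(progem_tab))
    progem_tab <- data.frame(gene = character(), rank = integer(),
                             tier = integer())
  .write_tsv(progem_tab, file.path(out_dir, "mediators.tsv"))
  .manifest(out_dir, "progem", params = config$progem,
            counts = list(n_loci = nrow(trans_reg),
                          n_candidates = if (is.null(progem_tab)) 0L
                          else nrow(progem_tab)),
            seed = config$seed)

  report <- list(
    n_variants = nrow(panel$variants),
    n_significant = n_sig,
    n_regions = if (is.null(regions)) 0L else nrow(regions),
    n_cis = sum(regions$label == "cis"),
    n_trans = sum(regions$label == "trans"),
    coloc = coloc_rows,
    mr = mr_rows[, c("protein", "disease", "status", "b_xy", "or_",
                     "or_lo", "or_hi", "p_xy", "fdr_q", "verdict")],
    mediators = progem_tab,
    meta = meta, regions = regions, conditional = conditional,
    disease = disease, eqtl = eqtl, panel = panel, design = design
  )
  invisible(report)
}
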