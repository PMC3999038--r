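# Orchestration: simulate -> pcr -> translate -> classify -> tree ->
# report as one configured, logged, reproducible run.

#' Choose the reading frame of an amplicon
#'
#' The forward primers sit in frame with the target's codons, so frame 0
#' on the forward strand is preferred whenever its translation is free of
#' internal stops; otherwise the frame with the fewest internal stops
#' (ties to the lower frame) is used.
#'
#' @param seq Amplicon nucleotide sequence, oriented by the forward
#'   primer.
#' @return List with `frame`, `protein`.
#' @export
choose_frame <- function(seq) {
  best <- NULL
  for (fr in 0:2) {
    prot <- translate_dna(seq, fr)
    body <- substr(prot, 1L, nchar(prot) - 1L)   # terminal stop tolerated
    stops <- lengths(regmatches(body, gregexpr("\\*", body)))
    if (fr == 0L && stops == 0L) {
      return(list(frame = 0L, protein = prot))
    }
    if (is.null(best) || stops < best$stops) {
      best <- list(frame = fr, protein = prot, stops = stops)
    }
  }
  list(frame = best$frame, protein = best$protein)
}

#' Classify one translated amplicon
#'
#' Dispatches on family: class II sequences get the Trp/Asp 2x2 call,
#' DyPs the peroxide-pocket call, UPOs the length grouping. All families
#' get a best-reference assignment over the family panel.
#'
#' @param protein Translated partial protein.
#' @param family "CLASS_II", "UPO" or "DYP".
#' @param anchors Named list of `anchor_spec` per family (CLASS_II, DYP).
#' @param panel Named character vector: family reference proteins.
#' @param ref_proteins Full panel across families (for the anchor
#'   reference lookup); defaults to `panel`.
#' @param params Alignment parameters.
#' @return One-row `data.frame` with the call fields.
#' @export
classify_amplicon <- function(protein, family, anchors, panel,
                              ref_proteins = panel,
                              params = align_params()) {
  length_aa <- nchar(gsub("\\*$", "", protein))
  out <- data.frame(family = family, length_aa = length_aa,
                    label = NA_character_, has_trp171 = NA,
                    has_asp175 = NA, has_arg329 = NA, has_leu354 = NA,
                    has_phe356 = NA, pocket_complete = NA,
                    group = NA_character_)
  clean <- gsub("\\*$", "", protein)
  if (family == "CLASS_II") {
    spec <- anchors[["CLASS_II"]]
    hits <- map_anchors(clean, spec, ref_proteins[[spec$ref_id]], params)
    call <- classify_class2(hits)
    out$label <- call$label
    out$has_trp171 <- call$has_trp171
    out$has_asp175 <- call$has_asp175
  } else if (family == "DYP") {
    spec <- anchors[["DYP"]]
    hits <- map_anchors(clean, spec, ref_proteins[[spec$ref_id]], params)
    call <- classify_dyp(hits, length_aa)
    out$has_arg329 <- call$has_arg329
    out$has_leu354 <- call$has_leu354
    out$has_phe356 <- call$has_phe356
    out$pocket_complete <- call$pocket_complete
    out$label <- if (call$pocket_complete) "POCKET_COMPLETE"
                 else "POCKET_INCOMPLETE"
  } else {
    call <- classify_upo(length_aa)
    out$group <- call$group
    out$label <- call$group
  }
  best <- assign_best_reference(clean, panel, params)
  out$best_ref <- best$ref_id
  out$best_identity <- best$identity
  out
}

# map a classifier label to the richness-table group vocabulary
.label_to_group <- function(family, label) {
  if (family == "DYP") return("DyP")
  if (family == "UPO") return("UPO")
  switch(label,
         MNP_LIKE = "MnP short/unclassified",
         LIP_LIKE_UNTYPICAL = "LiP",
         VP_LIKE = "VP",
         GP_LIKE = "GP",
         "MnP short/unclassified")
}

#' Run the full survey pipeline on synthetic or provided pools
#'
#' Stages: simulate (or load FASTA pools), in-silico PCR per family,
#' frame selection and translation, residue classification and
#' best-reference assignment, dereplication at DNA and protein level,
#' richness tabulation, per-family NJ trees with bootstrap supports, and
#' a cohort summary. All outputs are written atomically (temp file then
#' rename) into `out_dir`; `manifest.json` records the seed, parameters,
#' package version and output checksums, which suffices to reproduce the
#' run bit for bit.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()] driving simulation and seeding.
#' @param input Optional named list of site FASTA paths to analyze
#'   instead of simulated pools (each file one site; requires `panel`).
#' @param panel Reference panel (as from [make_reference_panel()]);
#'   defaults to the one generated from `config`.
#' @param max_mismatch Primer mismatch tolerance.
#' @param bootstrap_replicates Bootstrap replicates per family tree
#'   (0 disables trees).
#' @param min_support Newick display threshold for supports.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`amplicons`, `calls`, `dedup`, `richness`, `summary`, `trees`,
#'   `manifest`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         input = NULL, panel = NULL,
                         max_mismatch = 0L, bootstrap_replicates = 100L,
                         min_support = 50, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[peroxscan] ", ...)
  t_dir <- paste0(out_dir, ".tmp")
  unlink(t_dir, recursive = TRUE)
  dir.create(t_dir, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(t_dir, recursive = TRUE), add = TRUE)

  # stage: input
  if (is.null(input)) {
    say("simulating pools (seed ", config$seed, ")")
    sim <- generate_pools(config)
    pools <- sim$pools
    if (is.null(panel)) panel <- sim$panel
    write_simulation(sim, file.path(t_dir, "simulation"))
  } else {
    if (is.null(panel)) stop("a reference panel is required with raw input")
    pools <- do.call(rbind, lapply(names(input), function(site) {
      seqs <- read_fasta(input[[site]])
      if (length(seqs) == 0L) {
        stop("empty-input error: no records in ", input[[site]])
      }
      data.frame(id = names(seqs), seq = unname(seqs), site = site,
                 forest_type = site)
    }))
    sim <- NULL
  }
  if (is.null(pools) || nrow(pools) == 0L) stop("empty-input error: no records")

  # stage: pcr
  pairs <- peroxidase_primers()
  say("in-silico PCR over ", nrow(pools), " templates")
  amplicons <- do.call(rbind, lapply(names(pairs), function(fam) {
    templates <- setNames(pools$seq, pools$id)
    res <- amplify_pool(templates, pairs[[fam]], max_mismatch)
    if (nrow(res) == 0L) return(NULL)
    res$site <- pools$site[match(res$template_id, pools$id)]
    res$forest_type <- pools$forest_type[match(res$template_id, pools$id)]
    res
  }))
  if (is.null(amplicons)) amplicons <- data.frame()

  # stage: translate + classify
  calls <- NULL
  if (nrow(amplicons) > 0L) {
    say("translating and classifying ", nrow(amplicons), " amplicons")
    calls <- do.call(rbind, lapply(seq_len(nrow(amplicons)), function(i) {
      fam <- amplicons$family[i]
      fr <- choose_frame(amplicons$seq[i])
      fam_panel <- panel$proteins[panel$truth$ref_id[
        panel$truth$family == fam]]
      row <- classify_amplicon(fr$protein, fam, panel$anchors, fam_panel,
                               ref_proteins = panel$proteins)
      cbind(data.frame(id = amplicons$amplicon_id[i],
                       template_id = amplicons$template_id[i],
                       site = amplicons$site[i],
                       forest_type = amplicons$forest_type[i],
                       frame = fr$frame,
                       seq = amplicons$seq[i],
                       protein = gsub("\\*$", "", fr$protein)), row)
    }))
    calls$group <- vapply(seq_len(nrow(calls)), function(i) {
      .label_to_group(calls$family[i], calls$label[i])
    }, character(1))
  }

  # stage: dereplicate + richness + summary
  dedup <- richness <- summary_tab <- shared <- NULL
  if (!is.null(calls) && nrow(calls) > 0L) {
    dedup <- dedup_summary(calls)
    shared <- shared_across_sites(dedup$protein)
    richness <- richness_table(calls)
    summary_tab <- summarize_cohort(calls)
  }

  # stage: trees
  trees <- list()
  if (!is.null(calls) && bootstrap_replicates > 0L) {
    for (fam in unique(calls$family)) {
      prots <- calls$protein[calls$family == fam]
      ids <- calls$id[calls$family == fam]
      keep <- !duplicated(prots)
      prots <- setNames(prots[keep], ids[keep])
      if (length(prots) < 4L) next
      say("NJ + bootstrap (", bootstrap_replicates, " reps) for ", fam,
          ": ", length(prots), " unique proteins")
      msa <- progressive_msa(prots)
      tr <- tryCatch(
        bootstrap_support(msa, bootstrap_replicates,
                          seed = config$seed + match(fam, names(pairs))),
        error = function(e) NULL)
      if (!is.null(tr)) trees[[fam]] <- tr
    }
  }

  # stage: write bundle
  wr <- function(df, name) {
    utils::write.table(df, file.path(t_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(calls)) {
    wr(calls[, setdiff(names(calls), "seq")], "calls.tsv")
    wr(summary_tab, "summary.tsv")
    wr(data.frame(level = c("total", "unique_dna", "unique_protein"),
                  count = c(dedup$total, dedup$unique_dna,
                            dedup$unique_protein)), "dedup.tsv")
    wr(dedup$protein$clusters, "protein_clusters.tsv")
    if (nrow(shared) > 0L) wr(shared, "shared_across_sites.tsv")
    rt <- data.frame(group = rownames(richness), richness,
                     check.names = FALSE)
    wr(rt, "richness.tsv")
  }
  for (fam in names(trees)) {
    write_newick(trees[[fam]], file.path(t_dir, paste0("tree_", fam, ".nwk")),
                 min_support = min_support)
  }

  files <- sort(setdiff(list.files(t_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = "peroxscan",
    version = as.character(utils::packageVersion("peroxscan")),
    seed = config$seed,
    parameters = list(max_mismatch = max_mismatch,
                      bootstrap_replicates = bootstrap_replicates,
                      min_support = min_support,
                      mutation_rate = config$mutation_rate,
                      indel_rate = config$indel_rate,
                      n_sites = config$n_sites,
                      pool_size = as.list(config$pool_size)),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(t_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(t_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # atomic publish
  unlink(out_dir, recursive = TRUE)
  if (!dir.create(dirname(out_dir), recursive = TRUE, showWarnings = FALSE)) {
    # parent may already exist
  }
  ok <- file.rename(t_dir, out_dir)
  if (!ok) {  # cross-device fallback
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(t_dir, full.names = TRUE), out_dir,
              recursive = TRUE)
  }
  on.exit(NULL, add = FALSE)
  say("bundle written to ", out_dir)

  invisible(list(pools = pools, truth = if (!is.null(sim)) sim$truth,
                 panel = panel, amplicons = amplicons, calls = calls,
                 dedup = dedup, richness = richness,
                 summary = summary_tab, shared = shared, trees = trees,
                 manifest = manifest))
}
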