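# Synthetic amplicon-pool generator with full per-record ground truth.
#
# Reference panels carry family-specific catalytic anchors at fixed
# positions in synthetic reference numbering (decoupled from the real
# 171/175/329/354/356 coordinates, which belong to database reference
# proteins that are not reproduced here). Amplicons are built so that the
# shipped degenerate primer pairs recover them: a concrete stop-free
# expansion of the forward primer (20 nt) plus one pad base keeps the
# core codons in frame 0, and the reverse-complemented reverse-primer
# expansion closes the product. Translated partial-protein lengths follow
# the published ranges (UPO I.1 66-74 aa, UPO II 80-90 aa, DyP
# 128-144 aa, class II ~126-136 aa), which places the products at
# ~210 bp (UPO) and ~400 bp (class II, DyP).

# protein-coordinate anchor positions in the synthetic references
.SYN_ANCHORS <- list(
  CLASS_II = data.frame(position = c(60L, 64L), residue = c("W", "D"),
                        role = c("trp171", "asp175")),
  DYP = data.frame(position = c(30L, 55L, 57L), residue = c("R", "L", "F"),
                   role = c("arg329", "leu354", "phe356"))
)

#' Simulation configuration
#'
#' Defaults emulate the structure of a multi-site litter amplicon survey:
#' three families amplified per site, pools of clone-sized depth, modest
#' divergence of environmental variants from panel references, exact
#' duplicates shared within and across sites, and non-target decoys. The
#' class II label mix is MnP-dominated with small untypical-LiP and GP
#' fractions and no VP; DyP pocket residues are present at 0.98/0.98/0.91;
#' UPO references split 0.8/0.2 between the short (group I.1) and long
#' (group II) forms.
#'
#' @param seed Integer master seed; every random choice derives from it.
#' @param n_refs Named integer vector: panel size per family.
#' @param n_sites Number of simulated sites.
#' @param forest_types Forest-type label per site (recycled).
#' @param pool_size Named integer vector: target records per family per
#'   site.
#' @param ref_divergence Per-residue substitution rate separating panel
#'   references from their family scaffold (references within a family
#'   are homologous, as real family members are).
#' @param mutation_rate Per-nucleotide substitution probability applied
#'   to environmental variants (anchors and primer footprints preserved).
#' @param indel_rate Per-record probability of one 3-nt (codon) indel in
#'   the core region.
#' @param decoys_per_site Non-target sequences per site.
#' @param duplicate_rate Probability that a record is a copy of an
#'   earlier record of its family (possibly from another site).
#' @param dup_synonymous_frac Fraction of injected duplicates that are
#'   synonymous re-encodings (identical protein, freshly drawn codons)
#'   rather than exact copies; these reproduce the survey pattern of
#'   more unique DNA types than unique protein types.
#' @param class2_mix Label probabilities for class II references.
#' @param dyp_residue_probs Presence probability per DyP pocket residue.
#' @param upo_group_mix Group probabilities for UPO references.
#' @param class_ii_len,upo_i1_len,upo_ii_len,dyp_len Partial-protein
#'   length ranges (aa).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_refs = c(CLASS_II = 6L, UPO = 6L, DYP = 4L),
                       n_sites = 3L,
                       forest_types = c("Beech", "Spruce", "Oak"),
                       pool_size = c(CLASS_II = 10L, UPO = 10L, DYP = 8L),
                       ref_divergence = 0.12,
                       mutation_rate = 0.02,
                       indel_rate = 0.05,
                       decoys_per_site = 2L,
                       duplicate_rate = 0.15,
                       dup_synonymous_frac = 0.5,
                       class2_mix = c(MNP_LIKE = 0.75,
                                      LIP_LIKE_UNTYPICAL = 0.125,
                                      GP_LIKE = 0.125, VP_LIKE = 0),
                       dyp_residue_probs = c(arg329 = 0.98, leu354 = 0.98,
                                             phe356 = 0.91),
                       upo_group_mix = c(GROUP_I_1 = 0.8, GROUP_II = 0.2),
                       class_ii_len = c(126L, 136L),
                       upo_i1_len = c(66L, 74L),
                       upo_ii_len = c(80L, 90L),
                       dyp_len = c(128L, 144L)) {
  rates <- c(mutation_rate, indel_rate, duplicate_rate,
             dup_synonymous_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(sum(class2_mix) - 1) > 1e-9 || abs(sum(upo_group_mix) - 1) > 1e-9) {
    stop("label mixes must sum to 1")
  }
  cfg <- list(seed = as.integer(seed), n_refs = n_refs, n_sites = n_sites,
              forest_types = forest_types, pool_size = pool_size,
              ref_divergence = ref_divergence,
              mutation_rate = mutation_rate, indel_rate = indel_rate,
              decoys_per_site = decoys_per_site,
              duplicate_rate = duplicate_rate,
              dup_synonymous_frac = dup_synonymous_frac,
              class2_mix = class2_mix,
              dyp_residue_probs = dyp_residue_probs,
              upo_group_mix = upo_group_mix,
              class_ii_len = class_ii_len, upo_i1_len = upo_i1_len,
              upo_ii_len = upo_ii_len, dyp_len = dyp_len)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic stop-free concrete footprints for a primer pair:
# forward expansion + pad base with no stop in frame 0, and a reverse
# expansion whose reverse complement is stop-free in the amplicon frame
.footprints <- function(pair) {
  fill_n <- function(seqs) {
    # concrete fill of wildcard N positions, iterating a few options
    unlist(lapply(seqs, function(s) {
      if (!grepl("N", s)) return(s)
      vapply(c("G", "C", "A", "T"), function(b) gsub("N", b, s), "")
    }), use.names = FALSE)
  }
  fwd_opts <- fill_n(expand_degenerate(pair$forward))
  fwd <- NULL
  for (f in fwd_opts) for (pad in c("G", "C", "A", "T")) {
    cand <- paste0(f, pad)
    if (!grepl("\\*", translate_dna(cand))) {
      fwd <- cand
      break
    }
  }
  rev_opts <- fill_n(expand_degenerate(pair$reverse))
  tail_nt <- NULL
  for (r in rev_opts) {
    cand <- reverse_complement(r)
    if (nchar(cand) >= 3L && !grepl("\\*", translate_dna(cand))) {
      tail_nt <- cand
      break
    }
  }
  if (is.null(fwd) || is.null(tail_nt)) stop("no stop-free footprint found")
  list(fwd = fwd, tail = tail_nt,
       head_codons = nchar(fwd) %/% 3L,      # 7
       tail_codons = nchar(tail_nt) %/% 3L)  # 5 or 6
}

# codons per amino acid, from the standard genetic code
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

.backtranslate <- function(protein) {
  tab <- .codons_by_aa()
  paste(vapply(strsplit(protein, "")[[1]], function(aa) {
    opts <- tab[[aa]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

.random_protein <- function(n) {
  paste(sample(.AA_LETTERS, n, replace = TRUE), collapse = "")
}

# one synthetic reference derived from the family scaffold:
# returns list(protein, nt, label, flags, length)
.make_reference <- function(family, cfg, fp, scaffold_core) {
  if (family == "CLASS_II") {
    L <- sample(cfg$class_ii_len[1]:cfg$class_ii_len[2], 1L)
    label <- sample(names(cfg$class2_mix), 1L, prob = cfg$class2_mix)
    flags <- c(has_trp171 = label %in% c("LIP_LIKE_UNTYPICAL", "VP_LIKE"),
               has_asp175 = label %in% c("MNP_LIKE", "VP_LIKE"))
  } else if (family == "DYP") {
    L <- sample(cfg$dyp_len[1]:cfg$dyp_len[2], 1L)
    p <- cfg$dyp_residue_probs
    flags <- c(has_arg329 = runif(1) < p[["arg329"]],
               has_leu354 = runif(1) < p[["leu354"]],
               has_phe356 = runif(1) < p[["phe356"]])
    label <- if (all(flags)) "POCKET_COMPLETE" else "POCKET_INCOMPLETE"
  } else {
    label <- sample(names(cfg$upo_group_mix), 1L, prob = cfg$upo_group_mix)
    rng <- if (label == "GROUP_I_1") cfg$upo_i1_len else cfg$upo_ii_len
    L <- sample(rng[1]:rng[2], 1L)
    flags <- logical(0)
  }
  n_core <- L - fp$head_codons - fp$tail_codons
  stopifnot(n_core > 0L, n_core <= length(scaffold_core))
  anchors <- .SYN_ANCHORS[[family]]
  anchor_core <- if (is.null(anchors)) integer(0)
                 else anchors$position - fp$head_codons
  # homologous family member: scaffold prefix of the right length,
  # substituted at the reference-divergence rate away from the anchors
  core <- scaffold_core[seq_len(n_core)]
  hit <- setdiff(which(runif(n_core) < cfg$ref_divergence), anchor_core)
  for (i in hit) core[i] <- sample(setdiff(.AA_LETTERS, core[i]), 1L)
  if (!is.null(anchors)) {
    for (k in seq_len(nrow(anchors))) {
      expected <- anchors$residue[k]
      core[anchor_core[k]] <- if (flags[[k]]) expected else {
        # an ablated Mn-binding site must not stay acidic
        avoid <- if (expected == "D") c("D", "E") else expected
        sample(setdiff(.AA_LETTERS, avoid), 1L)
      }
    }
  }
  core_nt <- .backtranslate(paste(core, collapse = ""))
  nt <- paste0(fp$fwd, core_nt, fp$tail)
  list(protein = translate_dna(nt, 0L), nt = nt, label = label,
       flags = flags, length_aa = L)
}

.panel_impl <- function(cfg) {
  pairs <- peroxidase_primers()
  panel <- list(proteins = character(0), nucleotides = character(0))
  truth <- list()
  anchors <- list()
  footprints <- lapply(pairs, .footprints)
  for (family in names(cfg$n_refs)) {
    fp <- footprints[[family]]
    # family scaffold: the common ancestor all panel members (and hence
    # all environmental variants) are diverged copies of
    max_L <- switch(family, CLASS_II = cfg$class_ii_len[2],
                    UPO = max(cfg$upo_i1_len[2], cfg$upo_ii_len[2]),
                    DYP = cfg$dyp_len[2])
    scaffold <- strsplit(.random_protein(
      max_L - fp$head_codons - fp$tail_codons), "")[[1]]
    # a canonical anchor reference with every expected residue present
    ids <- c(paste0(family, "_ANCHORREF"),
             sprintf("%s_REF%02d", family, seq_len(cfg$n_refs[[family]])))
    for (i in seq_along(ids)) {
      if (i == 1L) {
        # force all anchors present (class II: VP-like reference)
        sub <- cfg
        sub$class2_mix <- c(MNP_LIKE = 0, LIP_LIKE_UNTYPICAL = 0,
                            GP_LIKE = 0, VP_LIKE = 1)
        sub$dyp_residue_probs <- c(arg329 = 1, leu354 = 1, phe356 = 1)
        sub$ref_divergence <- 0   # the anchor reference IS the scaffold
        ref <- .make_reference(family, sub, fp, scaffold)
      } else {
        ref <- .make_reference(family, cfg, fp, scaffold)
      }
      panel$proteins[ids[i]] <- ref$protein
      panel$nucleotides[ids[i]] <- ref$nt
      row <- data.frame(ref_id = ids[i], family = family,
                        intended_label = ref$label,
                        length_aa = ref$length_aa)
      for (fl in names(ref$flags)) row[[fl]] <- ref$flags[[fl]]
      truth[[length(truth) + 1L]] <- row
    }
    if (!is.null(.SYN_ANCHORS[[family]])) {
      anchors[[family]] <- anchor_spec(
        ref_id = ids[1], family = family, anchors = .SYN_ANCHORS[[family]],
        numbering_source = "synthetic reference numbering")
    }
  }
  flag_cols <- c("has_trp171", "has_asp175", "has_arg329", "has_leu354",
                 "has_phe356")
  truth <- do.call(rbind, lapply(truth, function(df) {
    for (col in flag_cols) if (!col %in% names(df)) df[[col]] <- NA
    df[, c("ref_id", "family", "intended_label", "length_aa", flag_cols)]
  }))
  rownames(truth) <- NULL
  list(proteins = panel$proteins, nucleotides = panel$nucleotides,
       anchors = anchors, truth = truth, footprints = footprints)
}

#' Generate a synthetic reference panel
#'
#' Random partial peroxidase proteins with family-specific catalytic
#' residues implanted (or ablated, following the configured label mix) at
#' fixed panel positions, back-translated through uniformly chosen
#' synonymous codons and wrapped in primer-compatible footprints so that
#' [amplify()] recovers the insert. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `proteins`, `nucleotides` (named vectors), `anchors`
#'   (named list of `anchor_spec`), `truth` (per-reference table) and
#'   `footprints`.
#' @export
make_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .panel_impl(config)
}

#' Mutate a sequence with positional preservation
#'
#' Per-site substitution with probability `rate` (uniform over the
#' alternative letters), plus at most one indel of `indel_unit`
#' characters with probability `indel_rate`. Positions in `preserve`
#' (and, for deletions, windows touching them) are never altered;
#' insertions are placed outside preserved runs. With `indel_unit = 3`
#' on nucleotide sequences the reading frame downstream of the indel is
#' kept.
#'
#' @param seq Sequence string.
#' @param rate Per-position substitution probability.
#' @param indel_rate Per-call indel probability.
#' @param preserve Integer positions that must stay untouched.
#' @param alphabet "nt" or "aa".
#' @param indel_unit Indel length in characters.
#' @param seed Optional seed for a reproducible single call.
#' @return List with `seq`, `n_sub`, `n_indel`.
#' @export
mutate_seq <- function(seq, rate, indel_rate = 0, preserve = integer(0),
                       alphabet = c("nt", "aa"), indel_unit = 1L,
                       seed = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(rate >= 0, rate <= 1, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  letters_all <- if (alphabet == "nt") c("A", "C", "G", "T") else .AA_LETTERS
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, preserve)
  for (i in hit) {
    chars[i] <- sample(setdiff(letters_all, chars[i]), 1L)
  }
  n_indel <- 0L
  if (indel_rate > 0 && runif(1) < indel_rate) {
    allowed <- setdiff(seq_len(n - indel_unit + 1L),
                       unlist(lapply(preserve, function(p) {
                         (p - indel_unit + 1L):p
                       })))
    allowed <- allowed[allowed >= 1L]
    if (length(allowed) > 0L) {
      pos <- allowed[sample.int(length(allowed), 1L)]
      if (runif(1) < 0.5) {
        chars <- chars[-(pos:(pos + indel_unit - 1L))]
      } else {
        ins <- sample(letters_all, indel_unit, replace = TRUE)
        chars <- append(chars, ins, after = pos - 1L)
      }
      n_indel <- 1L
    }
  }
  list(seq = paste(chars, collapse = ""), n_sub = length(hit),
       n_indel = n_indel)
}

# nucleotide positions that must survive mutation: both primer
# footprints and every anchor codon
.preserve_positions <- function(nt, family, fp) {
  n <- nchar(nt)
  keep <- c(seq_len(nchar(fp$fwd)), (n - nchar(fp$tail) + 1L):n)
  anchors <- .SYN_ANCHORS[[family]]
  if (!is.null(anchors)) {
    for (p in anchors$position) {
      keep <- c(keep, (3L * p - 2L):(3L * p))
    }
  }
  sort(unique(keep))
}

.random_decoy <- function(pairs) {
  for (try in 1:20) {
    len <- sample(200:450, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    n_amp <- sum(vapply(pairs, function(p) nrow(amplify(s, p)), integer(1)))
    if (n_amp == 0L) return(s)
  }
  stop("could not generate a primer-free decoy")  # practically unreachable
}

#' Generate per-site amplicon pools with ground truth
#'
#' Each pool mixes mutated target amplicons (with intact primer
#' footprints and preserved anchor codons, so the intended labels remain
#' the truth), exact duplicates injected within and across sites, and
#' decoys without primer sites. Fully deterministic under the config
#' seed: the same configuration reproduces identical pools and truth.
#'
#' @param config A [sim_config()].
#' @return List with `pools` (`data.frame`: `id`, `seq`, `site`,
#'   `forest_type`), `truth` (per-record table incl. decoys), `panel`
#'   (see [make_reference_panel()]).
#' @export
generate_pools <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- .panel_impl(config)
  pairs <- peroxidase_primers()
  sites <- sprintf("site%02d", seq_len(config$n_sites))
  ftypes <- rep(config$forest_types, length.out = config$n_sites)
  pools <- list()
  truth <- list()
  emitted <- list()  # per family: data.frame(id, seq, truth row index)
  for (si in seq_along(sites)) {
    site <- sites[si]
    for (family in names(config$pool_size)) {
      fp <- panel$footprints[[family]]
      ref_ids <- panel$truth$ref_id[panel$truth$family == family]
      for (k in seq_len(config$pool_size[[family]])) {
        id <- sprintf("%s_%s_%03d", site, family, k)
        prior <- emitted[[family]]
        if (!is.null(prior) && nrow(prior) > 0L &&
            runif(1) < config$duplicate_rate) {
          src <- prior[sample.int(nrow(prior), 1L), ]
          seq_out <- src$seq
          if (runif(1) < config$dup_synonymous_frac) {
            # synonymous re-encode: same protein, fresh codons for the
            # core; primer footprints stay verbatim
            head_nt <- nchar(fp$fwd)
            tail_nt <- nchar(fp$tail)
            core_nt <- substr(src$seq, head_nt + 1L,
                              nchar(src$seq) - tail_nt)
            seq_out <- paste0(substr(src$seq, 1L, head_nt),
                              .backtranslate(translate_dna(core_nt)),
                              substr(src$seq,
                                     nchar(src$seq) - tail_nt + 1L,
                                     nchar(src$seq)))
          }
          tr <- truth[[src$truth_idx]]
          row <- tr
          row$id <- id
          row$site <- site
          row$forest_type <- ftypes[si]
          row$duplicate_of <- src$id
          truth[[length(truth) + 1L]] <- row
          pools[[length(pools) + 1L]] <- data.frame(
            id = id, seq = seq_out, site = site, forest_type = ftypes[si])
          emitted[[family]] <- rbind(prior, data.frame(
            id = id, seq = seq_out, truth_idx = length(truth)))
          next
        }
        ref_id <- ref_ids[sample.int(length(ref_ids), 1L)]
        nt <- panel$nucleotides[[ref_id]]
        keep <- .preserve_positions(nt, family, fp)
        # guard indels that would push a UPO out of its group window or
        # a family out of its published length range
        mut <- mutate_seq(nt, config$mutation_rate, config$indel_rate,
                          preserve = keep, alphabet = "nt",
                          indel_unit = 3L)
        tr_ref <- panel$truth[panel$truth$ref_id == ref_id, , drop = FALSE]
        new_len <- nchar(mut$seq) %/% 3L
        rng <- switch(family,
                      CLASS_II = config$class_ii_len,
                      DYP = config$dyp_len,
                      UPO = if (tr_ref$intended_label == "GROUP_I_1")
                              config$upo_i1_len else config$upo_ii_len)
        if (mut$n_indel > 0L && (new_len < rng[1] || new_len > rng[2])) {
          mut <- mutate_seq(nt, config$mutation_rate, 0,
                            preserve = keep, alphabet = "nt")
        }
        row <- tr_ref
        names(row)[names(row) == "ref_id"] <- "source_ref"
        row$id <- id
        row$site <- site
        row$forest_type <- ftypes[si]
        row$length_aa <- nchar(mut$seq) %/% 3L
        row$n_sub <- mut$n_sub
        row$n_indel <- mut$n_indel
        row$duplicate_of <- NA_character_
        truth[[length(truth) + 1L]] <- row
        pools[[length(pools) + 1L]] <- data.frame(
          id = id, seq = mut$seq, site = site, forest_type = ftypes[si])
        emitted[[family]] <- rbind(emitted[[family]], data.frame(
          id = id, seq = mut$seq, truth_idx = length(truth)))
      }
    }
    for (d in seq_len(config$decoys_per_site)) {
      id <- sprintf("%s_DECOY_%03d", site, d)
      pools[[length(pools) + 1L]] <- data.frame(
        id = id, seq = .random_decoy(pairs), site = site,
        forest_type = ftypes[si])
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, site = site, forest_type = ftypes[si], family = "DECOY",
        source_ref = NA_character_, intended_label = "DECOY",
        length_aa = NA_integer_, has_trp171 = NA, has_asp175 = NA,
        has_arg329 = NA, has_leu354 = NA, has_phe356 = NA,
        n_sub = NA_integer_, n_indel = NA_integer_,
        duplicate_of = NA_character_)
    }
  }
  cols <- c("id", "site", "forest_type", "family", "source_ref",
            "intended_label", "length_aa", "has_trp171", "has_asp175",
            "has_arg329", "has_leu354", "has_phe356", "n_sub", "n_indel",
            "duplicate_of")
  truth <- do.call(rbind, lapply(truth, function(df) {
    if (!"source_ref" %in% names(df)) df$source_ref <- NA_character_
    if (!"n_sub" %in% names(df)) df$n_sub <- 0L
    if (!"n_indel" %in% names(df)) df$n_indel <- 0L
    if (!"duplicate_of" %in% names(df)) df$duplicate_of <- NA_character_
    df[, cols]
  }))
  pools <- do.call(rbind, pools)
  rownames(truth) <- rownames(pools) <- NULL
  list(pools = pools, truth = truth, panel = panel)
}

#' Write a simulation to disk
#'
#' Emits one FASTA per site, the reference FASTA pair (nucleotide and
#' protein), the anchor YAML and the truth TSV.
#'
#' @param sim Output of [generate_pools()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (site in unique(sim$pools$site)) {
    sub <- sim$pools[sim$pools$site == site, , drop = FALSE]
    write_fasta(setNames(sub$seq, sub$id),
                file.path(dir, paste0(site, ".fasta")))
  }
  write_fasta(sim$panel$nucleotides, file.path(dir, "references_nt.fasta"))
  write_fasta(sim$panel$proteins, file.path(dir, "references_aa.fasta"))
  anchors <- lapply(sim$panel$anchors, function(a) {
    pos <- as.list(setNames(
      lapply(seq_len(nrow(a$anchors)), function(i) {
        list(residue = a$anchors$residue[i], role = a$anchors$role[i])
      }), a$anchors$position))
    list(ref_id = a$ref_id, family = a$family,
         numbering_source = a$numbering_source, positions = pos)
  })
  yaml::write_yaml(list(anchors = unname(anchors)),
                   file.path(dir, "anchors.yaml"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
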