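# Rule-based functional typing of translated amplicons.
#
# Class II peroxidases are typed by two catalytic anchors: the surface
# tryptophan that oxidizes high-redox aromatics (homolog of Trp-171 in
# P. chrysosporium LiPH8) and the acidic Mn(2+)-binding aspartate
# (homolog of Asp-175 in P. chrysosporium MnP1). DyPs are scored for the
# three-residue H2O2-binding pocket (Arg-329, Leu-354, Phe-356 in
# B. adusta DyP 3MM3 numbering). UPOs carry no known diagnostic residue
# in the amplified region and are grouped by partial-protein length.

.CLASS2_LABELS <- c("MNP_LIKE", "LIP_LIKE_UNTYPICAL", "VP_LIKE", "GP_LIKE")

#' Type a class II peroxidase amplicon from its two catalytic anchors
#'
#' The label is a pure function of residue presence: Asp without Trp is
#' MnP-like; Trp without Asp is an "untypical" LiP (residue evidence
#' alone cannot place it in the canonical LiP clade - that upgrade is a
#' phylogenetic decision); both present is VP-like; neither is
#' GP-like. GAP and ABSENT anchor states count as "residue not present":
#' a partial sequence lacking the site carries no evidence for it.
#'
#' @param hits `data.frame` from [map_anchors()] containing rows with
#'   roles `"trp171"` and `"asp175"`; alternatively pass logicals via
#'   `has_trp`/`has_asp`.
#' @param has_trp,has_asp Direct logical overrides (used when `hits` is
#'   NULL).
#' @param accept_glu Also accept glutamate at the Mn-binding anchor
#'   (the site is acidic in versatile peroxidases); default FALSE,
#'   matching the aspartate-specific reading.
#' @return List of class `class2_call`: `label`, `has_trp171`,
#'   `has_asp175`, `evidence` (the hits, when given).
#' @export
classify_class2 <- function(hits = NULL, has_trp = NULL, has_asp = NULL,
                            accept_glu = FALSE) {
  if (!is.null(hits)) {
    trp <- hits[hits$role == "trp171", , drop = FALSE]
    asp <- hits[hits$role == "asp175", , drop = FALSE]
    if (nrow(trp) != 1L || nrow(asp) != 1L) {
      stop("hits must contain exactly one trp171 and one asp175 row")
    }
    has_trp <- trp$matches_expected
    has_asp <- asp$matches_expected ||
      (accept_glu && identical(asp$query_residue, "E"))
  }
  stopifnot(is.logical(has_trp), is.logical(has_asp))
  label <- if (has_asp && !has_trp) "MNP_LIKE"
           else if (has_trp && !has_asp) "LIP_LIKE_UNTYPICAL"
           else if (has_trp && has_asp) "VP_LIKE"
           else "GP_LIKE"
  structure(list(label = label, has_trp171 = has_trp, has_asp175 = has_asp,
                 evidence = hits), class = "class2_call")
}

#' @export
print.class2_call <- function(x, ...) {
  cat("<class2_call> ", x$label, " (Trp171: ", x$has_trp171,
      ", Asp175: ", x$has_asp175, ")\n", sep = "")
  invisible(x)
}

#' Score the DyP H2O2-binding pocket
#'
#' @param hits `data.frame` from [map_anchors()] with roles `"arg329"`,
#'   `"leu354"`, `"phe356"`.
#' @param length_aa Length of the translated partial protein.
#' @return List of class `dyp_call`: the three residue flags,
#'   `pocket_complete` (their conjunction) and `length_aa`.
#' @export
classify_dyp <- function(hits, length_aa) {
  get_flag <- function(role) {
    row <- hits[hits$role == role, , drop = FALSE]
    if (nrow(row) != 1L) stop("hits must contain exactly one ", role, " row")
    isTRUE(row$matches_expected)
  }
  r <- get_flag("arg329")
  l <- get_flag("leu354")
  f <- get_flag("phe356")
  structure(list(has_arg329 = r, has_leu354 = l, has_phe356 = f,
                 pocket_complete = r && l && f,
                 length_aa = as.integer(length_aa)),
            class = "dyp_call")
}

#' @export
print.dyp_call <- function(x, ...) {
  cat("<dyp_call> pocket", if (x$pocket_complete) "complete" else "incomplete",
      sprintf("(R329 %s, L354 %s, F356 %s), %d aa\n",
              x$has_arg329, x$has_leu354, x$has_phe356, x$length_aa))
  invisible(x)
}

#' Group a UPO amplicon by partial-protein length
#'
#' The amplified region is 66-74 aa (mean 70) in group I.1 sequences and
#' 80-90 aa in the group II enzymes; lengths outside both windows are
#' UNASSIGNED. No diagnostic catalytic residue is known in this region,
#' so length is the only cue.
#'
#' @param length_aa Partial protein length (>= 1).
#' @param bounds List with `group_i1` and `group_ii` length windows.
#' @return List of class `upo_call`: `length_aa`, `group`.
#' @export
classify_upo <- function(length_aa,
                         bounds = list(group_i1 = c(66L, 74L),
                                       group_ii = c(80L, 90L))) {
  length_aa <- as.integer(length_aa)
  stopifnot(length_aa >= 1L)
  group <- if (length_aa >= bounds$group_i1[1] &&
               length_aa <= bounds$group_i1[2]) "GROUP_I_1"
           else if (length_aa >= bounds$group_ii[1] &&
                    length_aa <= bounds$group_ii[2]) "GROUP_II"
           else "UNASSIGNED"
  structure(list(length_aa = length_aa, group = group), class = "upo_call")
}

#' @export
print.upo_call <- function(x, ...) {
  cat("<upo_call>", x$group, sprintf("(%d aa)\n", x$length_aa))
  invisible(x)
}

#' Summarize a cohort of family calls
#'
#' Per-family counts and percentages of each label and residue flag.
#' Percentages are rounded to the nearest integer (the reporting style of
#' amplicon surveys), and every row states its denominator explicitly:
#' published headline percentages are ambiguous when the denominator
#' (all analyzed vs DNA-unique vs protein-unique sequences) is implicit.
#'
#' @param calls `data.frame` with a `family` column plus, per row, a
#'   `label` column and/or logical flag columns (`has_*`,
#'   `pocket_complete`, `group`).
#' @return `data.frame` with columns `family`, `metric`, `value`,
#'   `count`, `denominator`, `percent`.
#' @export
summarize_cohort <- function(calls) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L,
            "family" %in% names(calls))
  out <- list()
  for (fam in unique(calls$family)) {
    sub <- calls[calls$family == fam, , drop = FALSE]
    n <- nrow(sub)
    add <- function(metric, value, count) {
      out[[length(out) + 1L]] <<- data.frame(
        family = fam, metric = metric, value = as.character(value),
        count = count, denominator = n,
        percent = as.integer(round(100 * count / n)))
    }
    for (col in intersect(c("label", "group"), names(sub))) {
      tab <- table(sub[[col]])
      for (v in names(tab)) add(col, v, as.integer(tab[[v]]))
    }
    flags <- grep("^has_|^pocket_complete$", names(sub), value = TRUE)
    for (col in flags) {
      vals <- sub[[col]]
      if (!all(is.na(vals))) add(col, "TRUE", sum(vals, na.rm = TRUE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
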