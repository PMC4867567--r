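# HGVS-style CHM variant parsing, functional classification, genotype
# grouping and family-level mutation-spectrum counts.
#
# This is deliberately not a general HGVS grammar: it covers the coding-DNA
# dialects seen in CHM mutation reports (single-nucleotide substitutions,
# small del/ins/dup, intronic offsets, and gross exon-range deletions or
# duplications written with "?" breakpoints or kb ranges).

MUTATION_CLASSES <- c(
  "whole_gene_deletion", "exon_deletion", "exon_duplication", "start_codon",
  "nonsense", "frameshift", "splice_site", "missense", "other"
)

# Typographic dashes that appear in published variant tables.
normalize_hgvs <- function(x) {
  x <- stringr::str_replace_all(x, "[‐‑‒–—−]", "-")
  x <- trimws(x)
  x <- sub("^C\\.", "c.", x)
  sub(";$", "", x)
}

classify_variant_one <- function(hgvs_c, annotation) {
  h <- normalize_hgvs(hgvs_c)
  ann <- if (is.na(annotation)) "" else normalize_hgvs(annotation)
  res <- function(class, rep1 = FALSE, spans_start = FALSE) {
    list(
      hgvs_c = h, mutation_class = class,
      rep1_absent_predicted = rep1, spans_start = spans_start
    )
  }
  if (is.na(h) || !grepl("^c\\.", h)) {
    warn(paste0("unparseable HGVS string classified as 'other': ", hgvs_c))
    return(res("other"))
  }
  ann_absent <- grepl("REP-?1 absent|absent REP-?1", ann, ignore.case = TRUE)
  # Gross structural variants: exon-range del/dup with uncertain breakpoints.
  if (grepl("\\?|kb", h)) {
    starts_utr5 <- grepl("^c\\.-", h)
    if (grepl("dup$", h)) {
      return(res("exon_duplication"))
    }
    if (grepl("del$", h)) {
      ends_utr3 <- grepl("_\\*", h)
      if (starts_utr5 && ends_utr3) {
        return(res("whole_gene_deletion", rep1 = TRUE, spans_start = TRUE))
      }
      # deletion beginning 5' of c.1 removes the translation start
      return(res("exon_deletion",
        rep1 = starts_utr5 || ann_absent, spans_start = starts_utr5
      ))
    }
  }
  if (grepl("fs", ann)) {
    return(res("frameshift"))
  }
  if (grepl("\\*", ann)) {
    return(res("nonsense"))
  }
  if (grepl("start codon", ann, ignore.case = TRUE) ||
    grepl("^c\\.[1-3][ACGT]>", h)) {
    return(res("start_codon", rep1 = TRUE, spans_start = TRUE))
  }
  intronic <- grepl("[0-9]+[+-][0-9]", h) || grepl("[0-9]+[+-]\\(", h)
  if (intronic || grepl("splice|skip", ann, ignore.case = TRUE)) {
    return(res("splice_site", rep1 = ann_absent))
  }
  if (grepl("^p\\.[A-Za-z]{1,3}[0-9]+[A-Za-z]{1,3}$", ann)) {
    return(res("missense"))
  }
  if (grepl("beyond the premature stop", ann, ignore.case = TRUE)) {
    # a change downstream of a premature stop has no classifiable effect of
    # its own
    return(res("other"))
  }
  warn(paste0(
    "could not classify variant '", hgvs_c, "' (annotation '",
    annotation, "'); classified as 'other'"
  ))
  res("other")
}

#' Parse and classify CHM coding-DNA variants
#'
#' Classifies each HGVS c. string (with its optional protein-change
#' annotation) into a functional class by a deterministic rule cascade:
#' gross exon-range deletions/duplications are recognised from the HGVS
#' string itself (a deletion starting 5' of c.1 and ending 3' of the stop is
#' a whole-gene deletion; one starting 5' of c.1 removes the translation
#' start); then frameshift (`fs` in the annotation), nonsense (`*` at a
#' substituted residue), start-codon changes, splice-site changes (intronic
#' offset positions or splice/skip annotations) and single-residue missense
#' substitutions. Unparseable input yields class `"other"` with a warning,
#' never an error.
#'
#' @param hgvs_c Character vector of HGVS c. strings (typographic dashes are
#'   normalised; a leading `"C."` is accepted).
#' @param protein_annotation Optional character vector of protein-change
#'   annotations (e.g. `"p.Arg253*"`) or descriptive labels.
#' @return Tibble with columns `hgvs_c` (normalised), `protein_annotation`,
#'   `mutation_class` (factor over the class taxonomy),
#'   `rep1_absent_predicted` and `spans_start`.
#' @examples
#' parse_variant("c.757C>T", "p.Arg253*")
#' parse_variant("c.238C>T", "p.Leu80Phe")
#' @export
parse_variant <- function(hgvs_c, protein_annotation = NULL) {
  if (length(hgvs_c) == 0) {
    abort("parse_variant: no variants supplied")
  }
  if (is.null(protein_annotation)) {
    protein_annotation <- rep(NA_character_, length(hgvs_c))
  }
  protein_annotation <- as.character(protein_annotation)
  rows <- purrr::map2(hgvs_c, protein_annotation, classify_variant_one)
  tibble(
    hgvs_c = purrr::map_chr(rows, "hgvs_c"),
    protein_annotation = protein_annotation,
    mutation_class = factor(
      purrr::map_chr(rows, "mutation_class"),
      levels = MUTATION_CLASSES
    ),
    rep1_absent_predicted = purrr::map_lgl(rows, "rep1_absent_predicted"),
    spans_start = purrr::map_lgl(rows, "spans_start")
  )
}

genotype_group_one <- function(classes, rep1, spans_start) {
  if (length(classes) == 0 || all(is.na(classes))) {
    abort("assign_genotype_group: subject has no variants")
  }
  if (any(classes == "missense", na.rm = TRUE)) {
    return("missense")
  }
  no_rep1 <- classes %in% c("whole_gene_deletion", "start_codon") |
    (classes == "exon_deletion" & spans_start)
  if (all(no_rep1 & rep1)) {
    return("rep1_absent")
  }
  "other"
}

#' Assign genotype groups for genotype-phenotype comparison
#'
#' Subjects are partitioned into `missense` (any missense variant),
#' `rep1_absent` (all variants abolish REP-1 expression through whole-gene
#' deletion, deletion of the ATG start codon, or a start-codon change) and
#' `other` (premature truncation and the rest).
#'
#' @param cohort A cohort tibble.
#' @return The cohort with a `genotype_group` factor column added.
#' @export
assign_genotype_group <- function(cohort) {
  cohort <- as_cohort(cohort)
  grp <- purrr::pmap_chr(
    list(cohort$hgvs_c, cohort$hgvs_c_2,
         cohort$protein_change, cohort$protein_change_2),
    function(h1, h2, p1, p2) {
      hs <- c(h1, h2)
      ps <- c(p1, p2)
      keep <- !is.na(hs)
      v <- parse_variant(hs[keep], ps[keep])
      genotype_group_one(
        as.character(v$mutation_class), v$rep1_absent_predicted, v$spans_start
      )
    }
  )
  cohort$genotype_group <- factor(grp, levels = c("missense", "rep1_absent", "other"))
  cohort
}

#' Family-level mutation-spectrum counts
#'
#' Counts families per mutation class. A family with two variants in
#' different classes contributes one family to each class it contains, but
#' only one family to the total; duplicate subjects within a family are
#' counted once.
#'
#' @param records A cohort tibble, or any data frame with a family column
#'   (`family_id` or `family`) plus `hgvs_c`, `hgvs_c_2`, `protein_change`,
#'   `protein_change_2`.
#' @return Tibble with one row per mutation class: `mutation_class`,
#'   `n_families`; the number of distinct families is attached as attribute
#'   `"n_families_total"`.
#' @export
spectrum_counts <- function(records) {
  df <- as_tibble(records)
  fam_col <- intersect(c("family_id", "family"), names(df))[1]
  if (is.na(fam_col)) abort("spectrum_counts: no family_id column")
  for (col in c("hgvs_c_2", "protein_change", "protein_change_2")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  long <- dplyr::bind_rows(
    tibble(family = as.character(df[[fam_col]]), hgvs = as.character(df$hgvs_c),
           ann = as.character(df$protein_change)),
    tibble(family = as.character(df[[fam_col]]), hgvs = as.character(df$hgvs_c_2),
           ann = as.character(df$protein_change_2))
  ) |>
    dplyr::filter(!is.na(.data$hgvs), toupper(.data$hgvs) != NC_TOKEN)
  classes <- parse_variant(long$hgvs, long$ann)$mutation_class
  per_family <- tibble(family = long$family, mutation_class = classes) |>
    dplyr::distinct()
  counts <- per_family |>
    dplyr::count(.data$mutation_class, .drop = FALSE, name = "n_families")
  attr(counts, "n_families_total") <- dplyr::n_distinct(per_family$family)
  counts
}
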