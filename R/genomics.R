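#' Controlled vocabularies of coding variant consequences
#'
#' `hmf_coding_terms()` is the nine-term list of coding consequences counted
#' as a mutation in the metastatic-cohort analysis; the
#' `deleterious_truncating_terms()` subset keeps only the clearly
#' protein-truncating classes used when flagging deleterious variants.
#'
#' @return Character vector of consequence terms.
#' @export
hmf_coding_terms <- function() {
  c(
    "frameshift_variant", "stop_gained", "splice_acceptor_variant",
    "splice_donor_variant", "start_lost", "stop_lost",
    "missense_variant", "inframe_deletion", "inframe_insertion"
  )
}

#' @rdname hmf_coding_terms
#' @export
deleterious_truncating_terms <- function() {
  c(
    "frameshift_variant", "stop_gained",
    "splice_acceptor_variant", "splice_donor_variant", "start_lost"
  )
}

#' Infer a consequence term from an HGVS-protein change
#'
#' Minimal pattern rules covering the protein-change styles found in
#' targeted-panel reports: a `fs*N` (or `fs`) suffix maps to frameshift, a
#' change ending in `*` to stop gained, a `_splice` suffix to a splice
#' variant, `p.M1?`/loss of the initiator methionine to start lost, a
#' simple one-residue substitution to missense. Anything else — including
#' empty input — returns `"unknown"` and never errors.
#'
#' @param hgvs_p Character vector of protein changes (with or without the
#'   `p.` prefix).
#' @return Character vector of consequence terms (see [hmf_coding_terms()]),
#'   `"splice_variant"` for splice-suffix changes, or `"unknown"`.
#' @examples
#' parse_protein_change(c("p.M695Nfs*26", "p.K810*", "p.X180_splice", "p.H1047R"))
#' @export
parse_protein_change <- function(hgvs_p) {
  vapply(as.character(hgvs_p), function(x) {
    if (is.na(x) || !nzchar(x)) return("unknown")
    x <- sub("^p\\.", "", x)
    if (grepl("fs(\\*\\d+)?$", x)) return("frameshift_variant")
    if (grepl("_splice$", x)) return("splice_variant")
    if (grepl("^[A-Z]\\d+\\*$", x)) return("stop_gained")
    if (grepl("^M1[?]?$", x) || grepl("^M1[A-Z]$", x)) return("start_lost")
    if (grepl("^\\*\\d+[A-Z]", x)) return("stop_lost")
    if (grepl("^[A-Z]\\d+(del|dup)$", x)) return("inframe_deletion")
    if (grepl("^[A-Z]\\d+[A-Z]$", x)) return("missense_variant")
    "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Flag variants under a consequence rule set
#'
#' Classifies each variant record as qualifying or not under the chosen
#' rule set: `"hmf_coding"` accepts any of the nine coding consequence
#' terms, `"deleterious_truncating"` only clearly truncating ones. The
#' explicit `consequence` column is used when present; otherwise the term
#' is inferred from `protein_change` with [parse_protein_change()]. A
#' generic `"splice_variant"` (parsed from a `_splice` suffix, where
#' acceptor vs donor is not recoverable) counts as a splice consequence
#' under both rule sets. Records with neither a recognizable consequence
#' nor a parseable protein change are flagged `unknown` and do not qualify.
#'
#' @param variants Tibble with `sample_id`, `gene` and at least one of
#'   `consequence`, `protein_change`.
#' @param rule_set `"hmf_coding"` (default) or `"deleterious_truncating"`.
#' @return The input with `consequence_used` and logical `qualifies`
#'   columns appended.
#' @export
classify_consequence <- function(variants,
                                 rule_set = c("hmf_coding", "deleterious_truncating")) {
  rule_set <- match.arg(rule_set)
  stopifnot(is.data.frame(variants))
  has_cons <- "consequence" %in% names(variants)
  has_prot <- "protein_change" %in% names(variants)
  if (!has_cons && !has_prot) {
    stop("variants need a 'consequence' or 'protein_change' column", call. = FALSE)
  }
  cons <- if (has_cons) normalize_consequence(variants$consequence) else
    rep(NA_character_, nrow(variants))
  if (has_prot) {
    fill <- is.na(cons) | cons == "unknown"
    cons[fill] <- parse_protein_change(variants$protein_change[fill])
  }
  cons[is.na(cons)] <- "unknown"
  accepted <- if (rule_set == "hmf_coding") hmf_coding_terms() else
    deleterious_truncating_terms()
  splice_ok <- any(grepl("^splice", accepted))
  qualifies <- cons %in% accepted | (splice_ok & cons == "splice_variant")
  variants %>%
    dplyr::mutate(consequence_used = cons, qualifies = qualifies)
}

# Map free-text consequence labels onto the controlled vocabulary.
normalize_consequence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]", "_", x)
  x <- sub("_variants?$", "_variant", x)
  map <- c(
    frameshift = "frameshift_variant",
    frameshift_variant = "frameshift_variant",
    stop_gained = "stop_gained",
    stop_gained_variant = "stop_gained",
    nonsense = "stop_gained",
    splice_acceptor = "splice_acceptor_variant",
    splice_acceptor_variant = "splice_acceptor_variant",
    splice_donor = "splice_donor_variant",
    splice_donor_variant = "splice_donor_variant",
    splice_variant = "splice_variant",
    start_lost = "start_lost",
    start_lost_variant = "start_lost",
    stop_lost = "stop_lost",
    stop_lost_variant = "stop_lost",
    missense = "missense_variant",
    missense_variant = "missense_variant",
    inframe_deletion = "inframe_deletion",
    inframe_deletions = "inframe_deletion",
    inframe_insertion = "inframe_insertion",
    inframe_insertions = "inframe_insertion"
  )
  out <- unname(map[x])
  out[is.na(out) & !is.na(x) & nzchar(x)] <- "unknown"
  out
}

#' Copy-number state from a log-ratio
#'
#' Bands the copy-number log-ratio into deep deletion (homozygous loss,
#' CN < -1), shallow deletion (heterozygous loss, -1 <= CN < -0.4) and
#' unaltered (CN >= -0.4); gains collapse into the unaltered band.
#'
#' @param log_ratio Numeric copy-number log-ratio.
#' @return Factor with levels `deep_del`, `shallow_del`, `unaltered`.
#' @examples
#' classify_cn_logratio(c(-1.5, -0.9, 0))
#' @export
classify_cn_logratio <- function(log_ratio) {
  if (any(!is.finite(log_ratio) & !is.na(log_ratio))) {
    stop("log_ratio must be finite", call. = FALSE)
  }
  cut(log_ratio,
    breaks = c(-Inf, -1, -0.4, Inf),
    labels = c("deep_del", "shallow_del", "unaltered"),
    right = FALSE
  )
}

#' Deletion state from allele-specific copy numbers
#'
#' Homozygous deletion when both the minor and the major allele copy number
#' are below 0.01; heterozygous deletion when the minor allele copy number
#' is below 0.01 but the major is not; unaltered otherwise.
#'
#' @param minor_cn,major_cn Non-negative allele copy numbers (minor <=
#'   major).
#' @param threshold Copy-number threshold for a lost allele (default 0.01).
#' @return Factor with levels `hom_del`, `het_del`, `unaltered`.
#' @examples
#' classify_allele_cn(c(0, 0, 1), c(0, 1, 1))
#' @export
classify_allele_cn <- function(minor_cn, major_cn, threshold = 0.01) {
  if (any(minor_cn < 0 | major_cn < 0, na.rm = TRUE)) {
    stop("allele copy numbers must be non-negative", call. = FALSE)
  }
  if (any(minor_cn > major_cn, na.rm = TRUE)) {
    stop("minor_cn must not exceed major_cn", call. = FALSE)
  }
  out <- ifelse(minor_cn < threshold & major_cn < threshold, "hom_del",
    ifelse(minor_cn < threshold, "het_del", "unaltered")
  )
  factor(out, levels = c("hom_del", "het_del", "unaltered"))
}

#' Call single- and double-hit gene inactivation per sample
#'
#' Combines the mutation flag (any qualifying coding variant under the
#' chosen rule set) with the deletion state (allele-specific copy number
#' preferred; log-ratio bands used when allele CN is absent) into a
#' zygosity-aware category: `double_hit` is a qualifying mutation on top of
#' a heterozygous deletion (biallelic inactivation), `homozygous_deletion`
#' is loss of both copies, and `mutation_only` / `deletion_only` / `none`
#' cover the remaining states.
#'
#' @param variants Variant tibble (see [classify_consequence()]); may be
#'   `NULL` or empty.
#' @param copy_numbers Tibble with `sample_id`, `gene` and `log_ratio`
#'   and/or `minor_cn` + `major_cn`.
#' @param gene Gene symbol to call (default `"RB1"`).
#' @param rule_set Consequence rule set for the mutation flag.
#' @return A tibble with one row per sample seen in either table:
#'   `sample_id`, `gene`, `mutation_flag`, `deletion_flag` (heterozygous),
#'   `hom_del_flag`, `category`.
#' @export
call_double_hit <- function(variants, copy_numbers, gene = "RB1",
                            rule_set = c("hmf_coding", "deleterious_truncating")) {
  rule_set <- match.arg(rule_set)
  mut <- tibble::tibble(sample_id = character(), mutation_flag = logical())
  if (!is.null(variants) && nrow(variants) > 0) {
    mut <- variants %>%
      dplyr::filter(.data$gene == !!gene) %>%
      classify_consequence(rule_set = rule_set) %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarise(mutation_flag = any(.data$qualifies), .groups = "drop")
  }
  del <- tibble::tibble(
    sample_id = character(),
    deletion_flag = logical(), hom_del_flag = logical()
  )
  if (!is.null(copy_numbers) && nrow(copy_numbers) > 0) {
    cn <- copy_numbers %>% dplyr::filter(.data$gene == !!gene)
    has_allele <- all(c("minor_cn", "major_cn") %in% names(cn))
    has_lr <- "log_ratio" %in% names(cn)
    if (!has_allele && !has_lr) {
      stop("copy_numbers need minor_cn+major_cn or log_ratio", call. = FALSE)
    }
    state <- rep(NA_character_, nrow(cn))
    if (has_allele) {
      ok <- !is.na(cn$minor_cn) & !is.na(cn$major_cn)
      state[ok] <- as.character(classify_allele_cn(cn$minor_cn[ok], cn$major_cn[ok]))
    }
    if (has_lr) {
      # allele CN wins when both representations are present
      fill <- is.na(state) & !is.na(cn$log_ratio)
      lr <- as.character(classify_cn_logratio(cn$log_ratio[fill]))
      state[fill] <- c(
        deep_del = "hom_del", shallow_del = "het_del", unaltered = "unaltered"
      )[lr]
    }
    del <- cn %>%
      dplyr::mutate(.state = state) %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarise(
        deletion_flag = any(.data$.state == "het_del", na.rm = TRUE),
        hom_del_flag = any(.data$.state == "hom_del", na.rm = TRUE),
        .groups = "drop"
      )
  }
  out <- dplyr::full_join(mut, del, by = "sample_id") %>%
    dplyr::mutate(
      gene = gene,
      mutation_flag = dplyr::coalesce(.data$mutation_flag, FALSE),
      deletion_flag = dplyr::coalesce(.data$deletion_flag, FALSE),
      hom_del_flag = dplyr::coalesce(.data$hom_del_flag, FALSE),
      category = dplyr::case_when(
        .data$hom_del_flag ~ "homozygous_deletion",
        .data$mutation_flag & .data$deletion_flag ~ "double_hit",
        .data$mutation_flag ~ "mutation_only",
        .data$deletion_flag ~ "deletion_only",
        TRUE ~ "none"
      )
    ) %>%
    dplyr::arrange(.data$sample_id) %>%
    dplyr::select(
      "sample_id", "gene", "mutation_flag", "deletion_flag",
      "hom_del_flag", "category"
    )
  out
}

#' Exposure-association logistic models for biallelic inactivation
#'
#' Fits the two multivariable logistic regressions relating a patient's
#' tumor alteration state to the probability of prior CDK4/6-inhibitor
#' exposure: M1 models `exposed ~ mutation + deletion + mutation:deletion`
#' (the headline statistic is the interaction, i.e. the excess association
#' of the double hit beyond each single alteration) and M2 models
#' `exposed ~ double_hit` with a single indicator for
#' mutation-plus-deletion. Separation or non-convergence in either fit is
#' reported, never silently dropped.
#'
#' @param cohort Tibble with one row per patient and logical/0-1 columns
#'   `exposed`, `mutation`, `deletion`.
#' @return An object of class `association_models`: `m1` and `m2`
#'   ([logistic_fit] objects) plus `n`. [tidy()] stacks both fits.
#' @export
association_models <- function(cohort) {
  stopifnot(all(c("exposed", "mutation", "deletion") %in% names(cohort)))
  d <- cohort %>%
    dplyr::transmute(
      exposed = as.integer(as_binary_labels(.data$exposed)),
      mutation = as.integer(as_binary_labels(.data$mutation)),
      deletion = as.integer(as_binary_labels(.data$deletion)),
      double_hit = as.integer(.data$mutation == 1 & .data$deletion == 1)
    )
  if (length(unique(d$exposed)) < 2L) {
    stop("degenerate outcome: cohort must contain exposed and unexposed patients",
      call. = FALSE
    )
  }
  m1 <- logistic_fit(d, exposed ~ mutation * deletion)
  m2 <- logistic_fit(d, exposed ~ double_hit)
  structure(list(m1 = m1, m2 = m2, n = nrow(d)), class = "association_models")
}

#' @export
print.association_models <- function(x, ...) {
  cat("M1: exposed ~ mutation * deletion (n =", x$n, ")\n")
  print(x$m1$terms)
  cat("M2: exposed ~ double_hit\n")
  print(x$m2$terms)
  invisible(x)
}
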