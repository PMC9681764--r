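#' Normalize a count table to per-sample relative abundance
#'
#' Scales each sample's abundances to sum to `total` (percent by default),
#' the per-nodule normalization applied to contig and MAG count tables.
#' Normalization is idempotent.
#'
#' @param counts Long tibble with columns `feature`, `sample`, `abundance`
#'   (non-negative); extra columns (e.g. `site`) pass through.
#' @param total Target per-sample sum (100 for percent).
#'
#' @return The same tibble with `abundance` rescaled.
#' @examples
#' counts <- tibble::tibble(
#'   feature = c("a", "b", "c"), sample = "s1", abundance = c(2, 3, 5)
#' )
#' normalize_relative_abundance(counts)$abundance # 20 30 50
#' @export
normalize_relative_abundance <- function(counts, total = 100) {
  if (any(counts$abundance < 0)) abort("abundances must be non-negative.")
  sums <- counts |>
    group_by(.data$sample) |>
    summarise(s = sum(.data$abundance), .groups = "drop")
  zero <- sums$sample[sums$s == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero total abundance: %s",
                  paste(zero, collapse = ", ")))
  }
  counts |>
    group_by(.data$sample) |>
    mutate(abundance = .data$abundance / sum(.data$abundance) * total) |>
    ungroup()
}

#' Archaea:bacteria abundance ratios
#'
#' Sums relative abundance over archaeal and bacterial features per sample
#' and reports their ratio; features from other domains (or unassigned) are
#' excluded from the ratio but reported in the `other` column. Site-level
#' values are means over the site's samples.
#'
#' @param table Long abundance tibble (`feature`, `sample`, `site`,
#'   `abundance`).
#' @param taxonomy Tibble mapping `feature` to `domain` (values `"Archaea"`,
#'   `"Bacteria"`, anything else pooled as other).
#' @param by `"sample"` for per-sample ratios or `"site"` for site means.
#'
#' @return A tibble with `archaea`, `bacteria`, `other` summed abundances and
#'   `ratio`. A sample with zero bacterial abundance yields `Inf` with a
#'   warning.
#' @export
archaea_bacteria_ratio <- function(table, taxonomy,
                                   by = c("sample", "site")) {
  by <- match.arg(by)
  per_sample <- table |>
    left_join(select(taxonomy, "feature", "domain"), by = "feature") |>
    group_by(across(any_of(c("sample", "site")))) |>
    summarise(
      archaea = sum(.data$abundance[.data$domain %in% "Archaea"]),
      bacteria = sum(.data$abundance[.data$domain %in% "Bacteria"]),
      other = sum(.data$abundance) - .data$archaea - .data$bacteria,
      .groups = "drop"
    ) |>
    mutate(ratio = .data$archaea / .data$bacteria)
  if (any(is.infinite(per_sample$ratio))) {
    warn("sample(s) with zero bacterial abundance: ratio reported as Inf.")
  }
  if (by == "sample") {
    return(per_sample)
  }
  per_sample |>
    group_by(.data$site) |>
    summarise(
      archaea = mean(.data$archaea), bacteria = mean(.data$bacteria),
      other = mean(.data$other), ratio = mean(.data$ratio),
      .groups = "drop"
    )
}

#' Filter MAGs on assembly quality
#'
#' Keeps genomes meeting the standard draft-quality rule: completeness at or
#' above `min_completeness` and contamination at or below
#' `max_contamination` (both bounds inclusive).
#'
#' @param mags Tibble with columns `id`, `completeness`, `contamination`.
#' @param min_completeness,max_contamination Bounds in percent.
#'
#' @return The filtered tibble.
#' @export
filter_mags <- function(mags, min_completeness = 70, max_contamination = 5) {
  filter(mags,
         .data$completeness >= min_completeness,
         .data$contamination <= max_contamination)
}

#' Cluster MAGs into species and pick representatives
#'
#' Two genomes belong to the same species when their average nucleotide
#' identity is at least `min_ani` percent with aligned coverage of at least
#' `min_coverage` percent (both inclusive); species are the single-linkage
#' (connected-component) clusters of that graph. Each cluster's
#' representative is the genome maximizing `completeness - 5 * contamination`,
#' ties broken by input order.
#'
#' @param mags Tibble with `id`, `completeness`, `contamination`.
#' @param pairs Long tibble of pairwise comparisons: `id1`, `id2`, `ani`,
#'   `coverage`. Missing pairs are treated as below threshold.
#' @param min_ani,min_coverage Species thresholds, percent.
#'
#' @return `mags` with added `cluster` (integer species id) and
#'   `representative` (logical) columns.
#' @export
dereplicate_species <- function(mags, pairs,
                                min_ani = 95, min_coverage = 10) {
  edges <- pairs |>
    filter(.data$ani >= min_ani, .data$coverage >= min_coverage,
           .data$id1 %in% mags$id, .data$id2 %in% mags$id)
  g <- igraph::graph_from_data_frame(
    edges[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = mags$id)
  )
  comp <- igraph::components(g)$membership[mags$id]
  score <- mags$completeness - 5 * mags$contamination
  rep_idx <- tapply(seq_len(nrow(mags)), comp,
                    function(ix) ix[which.max(score[ix])])
  mags |>
    mutate(
      cluster = as.integer(comp),
      representative = seq_len(nrow(mags)) %in% unlist(rep_idx)
    )
}

#' Select specialized MAGs
#'
#' Specialized genomes are those whose mean relative abundance exceeds
#' `threshold` percent (strictly) in at least one site.
#'
#' @param table Long abundance tibble (`feature`, `sample`, `site`,
#'   `abundance` in percent).
#' @param threshold Mean-abundance cutoff, percent (strict `>`).
#'
#' @return Character vector of selected feature ids.
#' @export
select_specialized_mags <- function(table, threshold = 10) {
  table |>
    group_by(.data$feature, .data$site) |>
    summarise(mean_abundance = mean(.data$abundance), .groups = "drop") |>
    group_by(.data$feature) |>
    summarise(selected = any(.data$mean_abundance > threshold),
              .groups = "drop") |>
    filter(.data$selected) |>
    pull("feature")
}

abundance_matrix <- function(table) {
  wide <- table |>
    select("feature", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "abundance",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' d(i, j) = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj), computed with
#' `vegan::vegdist`; ranges over [0, 1] for non-negative profiles.
#'
#' @param table Long abundance tibble (`feature`, `sample`, `abundance`).
#'
#' @return A symmetric numeric matrix with zero diagonal, samples as
#'   dimnames.
#' @export
bray_curtis <- function(table) {
  m <- abundance_matrix(table)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Site labels aligned with a distance matrix
#' @noRd
sample_sites <- function(table, d) {
  map <- distinct(table, .data$sample, .data$site)
  setNames(map$site, map$sample)[rownames(d)]
}
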