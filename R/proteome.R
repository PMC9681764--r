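PKA_SETS <- list(
  # EMBOSS iep defaults
  emboss = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
             Nterm = 8.6, H = 6.5, K = 10.8, R = 12.5),
  # Sillero & Ribeiro (1989)
  sillero = c(Cterm = 3.2, D = 4.0, E = 4.5, C = 9.0, Y = 10.0,
              Nterm = 8.2, H = 6.4, K = 10.4, R = 12.0)
)

ACIDIC_GROUPS <- c("D", "E", "C", "Y", "Cterm")
BASIC_GROUPS <- c("H", "K", "R", "Nterm")

#' Side-chain and terminal pKa sets for the charge model
#'
#' @param name `"emboss"` (default) or `"sillero"`. Different published pKa
#'   tables shift absolute pI values by roughly 0.1-0.3 units; comparisons
#'   across tools must use a common set.
#'
#' @return A named numeric vector of class `halohab_pka` with entries
#'   `D`, `E`, `C`, `Y`, `H`, `K`, `R`, `Nterm`, `Cterm`.
#' @export
pka_set <- function(name = c("emboss", "sillero")) {
  name <- match.arg(name)
  pka <- PKA_SETS[[name]]
  stopifnot(all(pka > 0 & pka < 14))
  structure(pka, class = "halohab_pka", set = name)
}

count_ionizable <- function(sequences) {
  res <- c("D", "E", "C", "Y", "H", "K", "R")
  counts <- vapply(res, function(a) {
    stringr::str_count(sequences, stringr::fixed(a))
  }, numeric(length(sequences)))
  m <- matrix(counts, nrow = length(sequences),
              dimnames = list(NULL, res))
  cbind(m, Nterm = 1, Cterm = 1)
}

charge_from_counts <- function(counts, pH, pka) {
  pos <- 0
  for (g in BASIC_GROUPS) {
    pos <- pos + counts[, g] / (1 + 10^(pH - pka[[g]]))
  }
  neg <- 0
  for (g in ACIDIC_GROUPS) {
    neg <- neg + counts[, g] / (1 + 10^(pka[[g]] - pH))
  }
  pos - neg
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch charge model: each basic group (H, K, R, the free
#' N-terminus) contributes `1 / (1 + 10^(pH - pKa))` and each acidic group
#' (D, E, C, Y, the free C-terminus) contributes `-1 / (1 + 10^(pKa - pH))`.
#' Ambiguous or unknown residues (X, B, Z, U, O, ...) carry no charge.
#'
#' @param sequence A single amino-acid sequence (non-empty).
#' @param pH pH value(s) at which to evaluate the charge.
#' @param pka A [pka_set()].
#'
#' @return Net charge, vectorized over `pH`.
#' @export
net_charge <- function(sequence, pH, pka = pka_set()) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    abort("`sequence` must be a single non-empty string.")
  }
  counts <- count_ionizable(toupper(sequence))
  vapply(pH, function(p) charge_from_counts(counts, p, pka)[1], numeric(1))
}

#' Predict protein isoelectric points by bisection
#'
#' Finds the pH in [0, 14] where the net charge crosses zero (the charge is
#' strictly decreasing in pH, so the root is unique). Bisection stops when
#' the charge magnitude falls below `tol` or the bracket is narrower than
#' 1e-6 pH units; the returned pI satisfies `|net_charge(pI)| < 10 * tol`.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param pka A [pka_set()].
#' @param tol Charge tolerance at the returned root.
#'
#' @return Numeric vector of pI values (pH units).
#' @examples
#' predict_pi(c("DDDDDDDDDD", "KKKKKKKKKK"))
#' @export
predict_pi <- function(sequences, pka = pka_set(), tol = 1e-4) {
  if (length(sequences) == 0) return(numeric(0))
  if (any(is.na(sequences) | nchar(sequences) == 0)) {
    abort("sequences must be non-empty.")
  }
  counts <- count_ionizable(toupper(sequences))
  lo <- rep(0, length(sequences))
  hi <- rep(14, length(sequences))
  mid <- (lo + hi) / 2
  repeat {
    ch <- charge_from_counts(counts, mid, pka)
    up <- ch > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    mid <- (lo + hi) / 2
    if (all(abs(ch) < tol) || max(hi - lo) < 1e-6) break
  }
  mid
}

#' Abundance-weighted community mean isoelectric point
#'
#' The community pI signature: `sum(w_i * pI_i) / sum(w_i)` where the weight
#' of a protein defaults to the relative abundance of its parent contig.
#' With equal weights this is the arithmetic mean pI.
#'
#' @param proteins Tibble with a `sequence` column and optionally `weight`
#'   (missing weights default to 1) and a precomputed `pi` column (computed
#'   from `sequence` when absent).
#' @param pka A [pka_set()].
#'
#' @return The weighted mean pI (pH units).
#' @export
weighted_mean_pi <- function(proteins, pka = pka_set()) {
  w <- proteins[["weight"]] %||% rep(1, nrow(proteins))
  if (any(w < 0)) abort("weights must be non-negative.")
  if (sum(w) <= 0) abort("total weight must be positive.")
  pi_vals <- proteins[["pi"]] %||% predict_pi(proteins$sequence, pka)
  sum(w * pi_vals) / sum(w)
}

#' Potassium-transport (Trk) potential per sample
#'
#' Sums the relative abundance of features annotated with the Trk system
#' KEGG orthologs (trkH = K03498, trkA = K03499); a feature carrying both
#' KOs is counted once.
#'
#' @param annotations Tibble mapping `feature` to `ko` (one row per
#'   feature-KO pair).
#' @param table Long abundance tibble (`feature`, `sample`, optionally
#'   `site`, `abundance`).
#' @param kos KO identifiers defining the transport system.
#'
#' @return A tibble with one row per sample: `sample` (and `site` if
#'   present), `trk_abundance`.
#' @export
trk_potential <- function(annotations, table,
                          kos = c("K03498", "K03499")) {
  hits <- unique(annotations$feature[annotations$ko %in% kos])
  table |>
    group_by(across(any_of(c("sample", "site")))) |>
    summarise(
      trk_abundance = sum(.data$abundance[.data$feature %in% hits]),
      .groups = "drop"
    )
}

#' Osmoadaptation gene catalog
#'
#' Loads the strategy -> gene catalog used for presence/absence profiling of
#' osmoadaptation capabilities in MAGs: Trk potassium uptake (trkH, trkA),
#' sodium:solute symport (SSS family), compatible-solute uptake (OpuA, OpuC,
#' OpuD, OpuBD, BetT), glycerol utilization (glpK plus the GlpABC
#' dehydrogenase), trehalose biosynthesis (glgA, glgC, treX) and ectoine
#' biosynthesis (asd, ectB, lysC). The shipped table is plain TSV and can be
#' replaced or extended via `path`.
#'
#' @param path Optional path to a custom catalog TSV with columns
#'   `strategy`, `gene` and optional `ko`.
#'
#' @return A tibble with columns `strategy`, `gene`, `ko`.
#' @export
osmo_gene_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "osmo_gene_catalog.tsv",
                                package = "halohab", mustWork = TRUE)
  cat <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("strategy", "gene") %in% names(cat))) {
    abort("catalog must have 'strategy' and 'gene' columns.")
  }
  if (!"ko" %in% names(cat)) cat$ko <- NA_character_
  bad <- cat$gene[!grepl("^[A-Za-z][A-Za-z0-9_]*$", cat$gene)]
  if (length(bad) > 0 || any(is.na(cat$gene))) {
    abort(sprintf("unknown gene symbol(s) in catalog: %s",
                  paste(bad, collapse = ", ")))
  }
  dup <- cat |>
    distinct(.data$strategy, .data$gene) |>
    dplyr::count(.data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("gene(s) assigned to multiple strategies: %s",
                  paste(dup$gene, collapse = ", ")))
  }
  as_tibble(cat[, c("strategy", "gene", "ko")])
}

#' Osmoadaptation gene presence/absence profile
#'
#' Marks, for every MAG, which catalog genes are present among its
#' annotations.
#'
#' @param mag_annotations Tibble mapping `mag` to annotated `gene` symbols.
#' @param catalog An [osmo_gene_catalog()] tibble.
#' @param mags MAG ids to profile (defaults to those appearing in
#'   `mag_annotations`); list explicitly to include MAGs with no
#'   annotations, which yield all-absent rows.
#'
#' @return Long tibble: `mag`, `strategy`, `gene`, `present`.
#' @export
osmo_gene_profile <- function(mag_annotations,
                              catalog = osmo_gene_catalog(),
                              mags = unique(mag_annotations$mag)) {
  tidyr::expand_grid(mag = mags, catalog[, c("strategy", "gene")]) |>
    left_join(
      mag_annotations |> distinct(.data$mag, .data$gene) |>
        mutate(present = TRUE),
      by = c("mag", "gene")
    ) |>
    mutate(present = !is.na(.data$present))
}

#' Per-strategy completeness of osmoadaptation gene sets
#'
#' A strategy is "complete" in a MAG when every gene of the strategy is
#' present (e.g. glycerol utilization requires glpK and all of glpA, glpB,
#' glpC).
#'
#' @param profile Output of [osmo_gene_profile()].
#'
#' @return Tibble: `mag`, `strategy`, `n_present`, `n_genes`, `complete`.
#' @export
osmo_strategy_completeness <- function(profile) {
  profile |>
    group_by(.data$mag, .data$strategy) |>
    summarise(
      n_present = sum(.data$present),
      n_genes = dplyr::n(),
      complete = all(.data$present),
      .groups = "drop"
    )
}
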