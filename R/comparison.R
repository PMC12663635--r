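#' Curated reference gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols; uppercased and
#'   de-duplicated (human symbol convention), must be non-empty.
#' @param source Free-text provenance.
#' @export
reference_gene_set <- function(name, genes, source = "") {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene set: ", name, call. = FALSE)
  structure(list(name = name, genes = genes, source = source),
            class = "reference_gene_set")
}

#' @export
print.reference_gene_set <- function(x, ...) {
  cat(sprintf("reference_gene_set '%s': %d genes%s\n", x$name,
              length(x$genes),
              if (nzchar(x$source)) paste0(" (", x$source, ")") else ""))
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @param source Free-text provenance.
#' @export
read_gene_set <- function(path, name = NULL, source = path) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  reference_gene_set(name, lines, source)
}

as_gene_vec <- function(x) {
  if (inherits(x, "reference_gene_set")) x$genes
  else unique(toupper(trimws(as.character(x))))
}

#' Overlap summary of two gene sets
#'
#' Exact set arithmetic (case-insensitive on symbols) with Jaccard
#' similarity/distance and membership classes. Percentages follow the
#' study's rounding convention (nearest whole percent).
#'
#' @param a,b Character vectors or [reference_gene_set()]s; both non-empty.
#' @return `overlap_summary` list: `set_a_n`, `set_b_n`, `intersection_n`,
#'   `union_n`, `jaccard_similarity`, `jaccard_distance`, `both`, `a_only`,
#'   `b_only` (gene vectors), `pct_a_in_b`, `pct_b_in_a`.
#' @export
overlap <- function(a, b) {
  ga <- as_gene_vec(a); gb <- as_gene_vec(b)
  if (!length(ga) || !length(gb)) stop("empty gene set", call. = FALSE)
  both <- intersect(ga, gb)
  uni <- union(ga, gb)
  structure(list(
    set_a_n = length(ga), set_b_n = length(gb),
    intersection_n = length(both), union_n = length(uni),
    jaccard_similarity = length(both) / length(uni),
    jaccard_distance = 1 - length(both) / length(uni),
    both = sort(both), a_only = sort(setdiff(ga, gb)),
    b_only = sort(setdiff(gb, ga)),
    pct_a_in_b = round(100 * length(both) / length(ga)),
    pct_b_in_a = round(100 * length(both) / length(gb))),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "overlap: |A|=%d |B|=%d |A∩B|=%d (~%d%% of A)  Jaccard distance %.3f\n",
    x$set_a_n, x$set_b_n, x$intersection_n, x$pct_a_in_b,
    x$jaccard_distance))
  invisible(x)
}

#' Multi-database membership tally for two bait interactomes
#'
#' Counts, for every prey detected by either bait, how many of the supplied
#' reference databases contain it, then cross-tabulates the membership tiers
#' ("in >= 2 databases", "in all databases") against bait exclusivity
#' (both / a_only / b_only) — the bookkeeping behind statements such as
#' "identified in at least two lysosomal databases".
#'
#' @param preys_by_bait Named list of exactly two gene vectors (or
#'   [reference_gene_set()]s): the two interactomes to compare.
#' @param databases List of at least two [reference_gene_set()]s.
#' @return List with `per_prey` (gene, n_dbs, exclusivity class) and
#'   `tier_table` (tiers x {both, a_only, b_only} integer matrix).
#' @export
multi_db_membership <- function(preys_by_bait, databases) {
  if (length(preys_by_bait) != 2)
    stop("preys_by_bait must name exactly two interactomes", call. = FALSE)
  if (length(databases) < 2)
    stop("need at least two databases", call. = FALSE)
  a <- as_gene_vec(preys_by_bait[[1]]); b <- as_gene_vec(preys_by_bait[[2]])
  dbs <- lapply(databases, as_gene_vec)
  genes <- sort(union(a, b))
  n_dbs <- rowSums(vapply(dbs, function(d) genes %in% d,
                          logical(length(genes))))
  cls <- ifelse(genes %in% a & genes %in% b, "both",
                ifelse(genes %in% a, "a_only", "b_only"))
  per_prey <- data.frame(gene = genes, n_dbs = as.integer(n_dbs),
                         class = cls, stringsAsFactors = FALSE)
  tiers <- c(at_least_two = 2L, all_dbs = length(dbs))
  tier_table <- t(vapply(tiers, function(t) {
    sel <- per_prey$n_dbs >= t
    c(both = sum(sel & cls == "both"),
      a_only = sum(sel & cls == "a_only"),
      b_only = sum(sel & cls == "b_only"))
  }, integer(3)))
  list(per_prey = per_prey, tier_table = tier_table)
}

#' Hypergeometric over-representation of a gene set
#'
#' Exact upper-tail hypergeometric test of the overlap between a query set
#' and a reference set drawn from a universe of `universe_n` genes (the
#' natural universe for BioID is the union of all detected preys), with fold
#' enrichment over the expected overlap.
#'
#' @param query Character vector or [reference_gene_set()].
#' @param reference A [reference_gene_set()] (or character vector).
#' @param universe_n Universe size; must be at least `|query ∪ reference|`.
#' @return List: `overlap_n`, `expected`, `fold_enrichment`, `p_value`.
#' @export
overrepresentation <- function(query, reference, universe_n) {
  q <- as_gene_vec(query); r <- as_gene_vec(reference)
  if (universe_n < length(union(q, r)))
    stop("universe smaller than the union of query and reference",
         call. = FALSE)
  ov <- length(intersect(q, r))
  expected <- length(q) * length(r) / universe_n
  p <- stats::phyper(ov - 1, length(r), universe_n - length(r), length(q),
                     lower.tail = FALSE)
  list(overlap_n = ov, expected = expected,
       fold_enrichment = if (expected > 0) ov / expected else NA_real_,
       p_value = p)
}

#' @describeIn overrepresentation Test one query against several references
#'   and append Benjamini-Hochberg adjusted p-values.
#' @param references List of [reference_gene_set()]s.
#' @export
overrepresentation_table <- function(query, references, universe_n) {
  rows <- lapply(references, function(r) {
    res <- overrepresentation(query, r, universe_n)
    data.frame(reference = if (inherits(r, "reference_gene_set")) r$name
                           else NA_character_,
               reference_n = length(as_gene_vec(r)),
               overlap_n = res$overlap_n, expected = res$expected,
               fold_enrichment = res$fold_enrichment,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Dot-plot export of a scored table
#'
#' Encodes every scored bait(-condition)-prey pair the way the study's dot
#' plots do: colour is the control-subtracted average spectral count capped
#' at 50; node size is the pair's average count relative to the maximum for
#' that prey across all bait datasets (in `[0, 1]`); border class bins the
#' BFDR (black <= 0.01 < blue <= 0.05 < light_blue).
#'
#' @param scored A scored table from [score_experiment()].
#' @param high_confidence Optional character vector of prey ids; when given,
#'   only those preys are exported.
#' @param cap Colour cap, default 50.
#' @return data.frame: `bait_id`, `condition`, `prey_id`, `color_value`,
#'   `size_value`, `border_class`.
#' @export
dotplot_export <- function(scored, high_confidence = NULL, cap = 50) {
  s <- scored
  if (!is.null(high_confidence))
    s <- s[norm_sym(s$prey_id) %in% norm_sym(high_confidence), ,
           drop = FALSE]
  color <- pmin(pmax(s$avg_spec - s$ctrl_avg, 0), cap)
  prey_max <- tapply(s$avg_spec, s$prey_id, max)
  mx <- unname(prey_max[s$prey_id])
  size <- ifelse(mx > 0, s$avg_spec / mx, 0)
  border <- ifelse(s$bfdr <= 0.01, "black",
                   ifelse(s$bfdr <= 0.05, "blue", "light_blue"))
  data.frame(bait_id = s$bait_id, condition = s$condition,
             prey_id = s$prey_id, color_value = color, size_value = size,
             border_class = border, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Preys shared between two bait families
#'
#' Two constructions of a "shared interactome" across condition-specific
#' high-confidence sets: with `require_all_conditions = FALSE` a prey
#' counts as belonging to a family if it appears in any of that family's
#' sets (union before intersecting); with `TRUE` it must appear in every
#' set of both families. Both are reported because summary counts of this
#' kind depend on which construction is meant.
#'
#' @param sets_a,sets_b Lists of character vectors (one per dataset /
#'   condition) for the two bait families.
#' @param require_all_conditions See above.
#' @return Character vector of shared gene symbols (uppercased, sorted).
#' @export
shared_preys <- function(sets_a, sets_b, require_all_conditions = FALSE) {
  combine <- function(sets) {
    sets <- lapply(sets, as_gene_vec)
    if (require_all_conditions) Reduce(intersect, sets)
    else Reduce(union, sets)
  }
  sort(intersect(combine(sets_a), combine(sets_b)))
}
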