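#' Spectral-count experiment container
#'
#' Bundles the three SAINT-convention tables of a BioID experiment: the
#' interaction table (one row per run x prey with a positive spectral count),
#' the run manifest (bait identity, test/control role, cycling/ciliated
#' condition) and the prey annotation table. Preys absent from a run carry an
#' implicit spectral count of zero; [count_matrix()] materialises the full
#' run x prey grid.
#'
#' @param counts data.frame with columns `run_id`, `prey_id`, `count`
#'   (non-negative integers). `(run_id, prey_id)` pairs must be unique.
#' @param runs data.frame with columns `run_id`, `bait_id`, `role`
#'   (`"test"` or `"control"`) and `condition` (`"cycling"` or `"ciliated"`).
#'   Every run referenced by `counts` must appear exactly once.
#' @param preys data.frame with columns `prey_id`, `gene_symbol` and
#'   optionally `sequence_length`. Defaults to one row per prey seen in
#'   `counts` with the prey id reused as gene symbol.
#' @return An object of class `sc_experiment`.
#' @seealso [read_experiment()], [write_experiment()], [count_matrix()]
#' @export
sc_experiment <- function(counts, runs, preys = NULL) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  if (is.null(preys)) {
    ids <- sort(unique(as.character(counts$prey_id)))
    preys <- data.frame(prey_id = ids, gene_symbol = ids,
                        sequence_length = NA_integer_,
                        stringsAsFactors = FALSE)
  }
  preys <- as.data.frame(preys, stringsAsFactors = FALSE)
  if (is.null(preys$sequence_length)) preys$sequence_length <- NA_integer_
  x <- structure(list(counts = counts, runs = runs, preys = preys),
                 class = "sc_experiment")
  validate_sc_experiment(x)
}

validate_sc_experiment <- function(x) {
  counts <- x$counts; runs <- x$runs; preys <- x$preys
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(counts, c("run_id", "prey_id", "count"), "interaction")
  need(runs, c("run_id", "bait_id", "role", "condition"), "bait")
  need(preys, c("prey_id", "gene_symbol"), "prey")
  if (nrow(counts) == 0L) stop("no interactions", call. = FALSE)
  if (anyNA(counts$count) || any(counts$count < 0) ||
      any(counts$count != round(counts$count)))
    stop("spectral counts must be non-negative integers", call. = FALSE)
  key <- paste(counts$run_id, counts$prey_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- counts[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate (run, prey) row(s), e.g. (%s, %s)",
                 d$run_id[1], d$prey_id[1]), call. = FALSE)
  }
  if (anyDuplicated(runs$run_id))
    stop("duplicate run_id in bait manifest", call. = FALSE)
  if (!all(runs$role %in% c("test", "control")))
    stop("run role must be 'test' or 'control'", call. = FALSE)
  if (!all(runs$condition %in% c("cycling", "ciliated")))
    stop("run condition must be 'cycling' or 'ciliated'", call. = FALSE)
  orphan <- setdiff(unique(counts$run_id), runs$run_id)
  if (length(orphan))
    stop(sprintf("run(s) present in interactions but missing from bait manifest: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(preys$prey_id))
    stop("duplicate prey_id in prey table", call. = FALSE)
  orphan_prey <- setdiff(unique(counts$prey_id), preys$prey_id)
  if (length(orphan_prey))
    stop(sprintf("prey(s) present in interactions but missing from prey table: %s",
                 paste(utils::head(orphan_prey, 3), collapse = ", ")),
         call. = FALSE)
  x
}

#' @export
print.sc_experiment <- function(x, ...) {
  nb <- length(unique(x$runs$bait_id[x$runs$role == "test"]))
  cat(sprintf(
    "sc_experiment: %d runs (%d control), %d baits, %d preys, %d nonzero counts\n",
    nrow(x$runs), sum(x$runs$role == "control"), nb, nrow(x$preys),
    sum(x$counts$count > 0)))
  invisible(x)
}

#' Materialise the run x prey spectral-count grid
#'
#' @param x An [sc_experiment()].
#' @param run_ids Optional subset of runs (columns) to return.
#' @return Integer matrix, preys in rows (all annotated preys) and runs in
#'   columns; preys absent from a run are 0.
#' @export
count_matrix <- function(x, run_ids = NULL) {
  stopifnot(inherits(x, "sc_experiment"))
  if (is.null(run_ids)) run_ids <- x$runs$run_id
  bad <- setdiff(run_ids, x$runs$run_id)
  if (length(bad)) stop("unknown run_id: ", paste(bad, collapse = ", "))
  m <- matrix(0L, nrow(x$preys), length(run_ids),
              dimnames = list(x$preys$prey_id, run_ids))
  sel <- x$counts$run_id %in% run_ids
  cc <- x$counts[sel, , drop = FALSE]
  m[cbind(match(cc$prey_id, rownames(m)), match(cc$run_id, run_ids))] <-
    as.integer(cc$count)
  m
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (!length(lines)) stop(sprintf("%s file %s is empty", what, path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss))
    stop(sprintf("%s file %s lacks column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (length(lines) == 1L)
    return(stats::setNames(as.data.frame(matrix(character(), 0, length(header)),
                                         stringsAsFactors = FALSE), header))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1] + 1L
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields, got %d",
                 bad, path, length(header), nf[bad - 1L]), call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read a SAINT-convention interaction/bait/prey file triplet
#'
#' Files are tab-delimited UTF-8 with a header row. The interaction file has
#' columns `run_id`, `bait_id`, `prey_id`, `count`; the bait manifest has
#' `run_id`, `bait_id`, `role`, `condition`; the prey file has `prey_id`,
#' `gene_symbol` and optionally `sequence_length`. Malformed lines raise an
#' error naming the offending line number.
#'
#' @param interaction_path,bait_path,prey_path File paths. `prey_path` may be
#'   `NULL`, in which case a minimal prey table is derived from the
#'   interactions.
#' @return An [sc_experiment()].
#' @export
read_experiment <- function(interaction_path, bait_path, prey_path = NULL) {
  inter <- read_tsv_checked(interaction_path,
                            c("run_id", "bait_id", "prey_id", "count"),
                            "interaction")
  if (nrow(inter) == 0L)
    stop("no interactions in ", interaction_path, call. = FALSE)
  n <- suppressWarnings(as.numeric(inter$count))
  if (anyNA(n)) {
    bad <- which(is.na(n))[1] + 1L
    stop(sprintf("malformed line %d in %s: count '%s' is not a number",
                 bad, interaction_path, inter$count[bad - 1L]), call. = FALSE)
  }
  inter$count <- as.integer(round(n))
  runs <- read_tsv_checked(bait_path,
                           c("run_id", "bait_id", "role", "condition"), "bait")
  preys <- NULL
  if (!is.null(prey_path)) {
    preys <- read_tsv_checked(prey_path, c("prey_id", "gene_symbol"), "prey")
    if (!is.null(preys$sequence_length))
      preys$sequence_length <-
        suppressWarnings(as.integer(preys$sequence_length))
  }
  # bait identity in the interaction file must agree with the manifest
  bmap <- stats::setNames(runs$bait_id, runs$run_id)
  known <- inter$run_id %in% runs$run_id
  clash <- known & inter$bait_id != bmap[inter$run_id]
  if (any(clash)) {
    i <- which(clash)[1]
    stop(sprintf(
      "run %s is assigned to bait %s in the manifest but %s in the interaction file",
      inter$run_id[i], bmap[inter$run_id[i]], inter$bait_id[i]), call. = FALSE)
  }
  sc_experiment(inter[, c("run_id", "prey_id", "count")], runs, preys)
}

#' Write an experiment as a SAINT-convention file triplet
#'
#' Inverse of [read_experiment()]; only nonzero counts are written (zeros
#' remain implicit). Round-trips losslessly.
#'
#' @param x An [sc_experiment()].
#' @param interaction_path,bait_path,prey_path Output file paths.
#' @export
write_experiment <- function(x, interaction_path, bait_path, prey_path) {
  stopifnot(inherits(x, "sc_experiment"))
  cc <- x$counts[x$counts$count > 0, , drop = FALSE]
  cc <- cc[order(cc$run_id, cc$prey_id), , drop = FALSE]
  bmap <- stats::setNames(x$runs$bait_id, x$runs$run_id)
  inter <- data.frame(run_id = cc$run_id, bait_id = bmap[cc$run_id],
                      prey_id = cc$prey_id, count = cc$count,
                      stringsAsFactors = FALSE)
  utils::write.table(inter, interaction_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(x$runs, bait_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(x$preys, prey_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)
pack_vec <- function(v) vapply(v, function(e) paste(fmt_num(e), collapse = "|"), "")
unpack_vec <- function(s) lapply(strsplit(s, "|", fixed = TRUE), as.numeric)

#' Write / read a scored interaction table
#'
#' Mirrors the SAINT output convention: one row per bait-prey pair with the
#' per-replicate spectral counts, the replicate-averaged interaction
#' probability (`AvgP`), the mean test count (`AvgSpec`), the compressed
#' virtual-control counts and their mean, and the Bayesian false discovery
#' rate (`BFDR`). Rows are grouped by bait (then condition) and sorted by
#' ascending BFDR, ties broken by descending `AvgP` then prey id. Numbers are
#' written with full precision so the table round-trips losslessly through
#' [read_scored_table()].
#'
#' @param scored A scored table from [score_experiment()] (or any data.frame
#'   with its columns); must be non-empty.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
write_scored_table <- function(scored, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (is.null(nrow(scored)) || nrow(scored) == 0L)
    stop("scored table is empty", call. = FALSE)
  o <- order(scored$bait_id, scored$condition, scored$bfdr, -scored$avg_p,
             scored$prey_id)
  s <- scored[o, , drop = FALSE]
  out <- data.frame(
    Bait = s$bait_id, Condition = s$condition, Prey = s$prey_id,
    Spec = pack_vec(s$replicate_counts),
    AvgSpec = fmt_num(s$avg_spec),
    CtrlCounts = pack_vec(s$ctrl_counts),
    CtrlAvg = fmt_num(s$ctrl_avg),
    RepProb = pack_vec(s$replicate_probs),
    AvgP = fmt_num(s$avg_p),
    BFDR = fmt_num(s$bfdr),
    stringsAsFactors = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(scored)
}

#' @rdname write_scored_table
#' @export
read_scored_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(bait_id = df$Bait, condition = df$Condition,
                    prey_id = df$Prey, stringsAsFactors = FALSE)
  out$replicate_counts <- unpack_vec(df$Spec)
  out$replicate_probs <- unpack_vec(df$RepProb)
  out$ctrl_counts <- unpack_vec(df$CtrlCounts)
  out$avg_spec <- as.numeric(df$AvgSpec)
  out$ctrl_avg <- as.numeric(df$CtrlAvg)
  out$avg_p <- as.numeric(df$AvgP)
  out$bfdr <- as.numeric(df$BFDR)
  out
}
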