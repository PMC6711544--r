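# Plain-text serialization of landscapes and populations, graph export for
# network visualization, and the synthetic stand-in for the empirical
# eight-locus Aspergillus niger cross.
#
# Canonical landscape format (TSV): header comment lines '#L=', '#model=',
# '#seed=', '#bitstring=locus0-leftmost', then all 2^L rows 'bitstring<TAB>
# fitness' sorted by genotype index. A JSON dialect mirrors the same fields.

#' Convert genotype indices to bitstrings and back
#'
#' Bitstrings are written with the first locus (bit 0) leftmost.
#'
#' @param index genotype index vector.
#' @param L number of loci.
#' @param s character vector of 0/1 bitstrings.
#' @return character vector, or integer index vector respectively.
#' @export
to_bitstring <- function(index, L) {
  L <- .check_L(L)
  index <- .check_genotype(index, L)
  vapply(index, function(i)
    paste(bitwAnd(bitwShiftR(i, 0:(L - 1L)), 1L), collapse = ""),
    character(1))
}

#' @rdname to_bitstring
#' @export
from_bitstring <- function(s) {
  vapply(s, function(x) {
    bits <- as.integer(strsplit(x, "")[[1]])
    if (any(is.na(bits)) || any(!bits %in% 0:1))
      stop(sprintf("malformed bitstring '%s'", x), call. = FALSE)
    genotype_index(bits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read and write fitness landscapes
#'
#' The dialect is chosen from the file extension: `.json` for JSON,
#' anything else is the canonical TSV format. Fitness values are serialized
#' with 17 significant digits so that write-then-read round-trips exactly.
#' Malformed input (missing or duplicated bitstrings, fitness outside
#' `[0, 1]`, header/body length mismatch) is a diagnostic error.
#'
#' @param land a [fitness_landscape()].
#' @param path file path.
#' @return `read_landscape()` returns a [fitness_landscape()];
#'   `write_landscape()` returns `path` invisibly.
#' @export
write_landscape <- function(land, path) {
  .check_landscape(land)
  L <- land$L
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(L = L, model = land$model,
                seed = if (is.na(land$seed)) NULL else land$seed,
                bitstring = to_bitstring(0:(2^L - 1L), L),
                fitness = land$w)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#L=%d", L),
                 sprintf("#model=%s", land$model),
                 sprintf("#seed=%s", if (is.na(land$seed)) "NA" else land$seed),
                 "#bitstring=locus0-leftmost"), con)
    writeLines(sprintf("%s\t%.17g", to_bitstring(0:(2^L - 1L), L), land$w), con)
  }
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    L <- as.integer(obj$L)
    bits <- obj$bitstring
    w <- as.numeric(obj$fitness)
    model <- if (is.null(obj$model)) "custom" else obj$model
    seed <- if (is.null(obj$seed)) NA else obj$seed
  } else {
    lines <- readLines(path)
    headers <- grep("^#", lines, value = TRUE)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    geth <- function(key) {
      hit <- grep(paste0("^#", key, "="), headers, value = TRUE)
      if (length(hit) != 1) stop(sprintf("missing '#%s=' header", key), call. = FALSE)
      sub(paste0("^#", key, "="), "", hit)
    }
    L <- as.integer(geth("L"))
    model <- geth("model")
    seed_chr <- geth("seed")
    seed <- if (seed_chr == "NA") NA else as.numeric(seed_chr)
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed row: expected 'bitstring<TAB>fitness'", call. = FALSE)
    bits <- vapply(parts, `[[`, character(1), 1)
    w <- as.numeric(vapply(parts, `[[`, character(1), 2))
  }
  if (is.na(L) || L < 1) stop("invalid L header", call. = FALSE)
  if (any(nchar(bits) != L))
    stop("bitstring length does not match the L header", call. = FALSE)
  idx <- from_bitstring(bits)
  if (anyDuplicated(idx))
    stop(sprintf("duplicate bitstring '%s'", bits[duplicated(idx)][1]), call. = FALSE)
  if (length(idx) != 2^L) {
    missing_idx <- setdiff(0:(2^L - 1L), idx)
    stop(sprintf("missing %d row(s); first absent bitstring: %s",
                 length(missing_idx), to_bitstring(missing_idx[1], L)),
         call. = FALSE)
  }
  if (any(is.na(w)) || any(w < 0) || any(w > 1))
    stop("fitness values must be numbers in [0, 1]", call. = FALSE)
  worder <- numeric(2^L)
  worder[idx + 1L] <- w
  fitness_landscape(worder, L, model = model, seed = seed)
}

#' Export a landscape as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` and `<prefix>_edges.tsv` for consumption by
#' external graph tools. The node table lists every genotype with its
#' viability flag and robustness, plus (when given) stationary frequency,
#' recombination weight, and a suggested node-size column proportional to
#' the sixth power of the weight (or of the frequency when no weights are
#' given) -- the convention that makes differences between genotypes
#' conspicuous in network figures. The edge table lists each pair of viable
#' genotypes at Hamming distance 1 once; with a state the suggested edge
#' width is the frequency of the more populated endpoint.
#'
#' @param land a [fitness_landscape()].
#' @param prefix output path prefix.
#' @param state optional stationary frequency vector.
#' @param weights optional recombination weight vector.
#' @return invisibly, a list with the two file paths.
#' @export
export_graph <- function(land, prefix, state = NULL, weights = NULL) {
  .check_landscape(land)
  L <- land$L
  idx <- 0:(2^L - 1L)
  nodes <- data.frame(bitstring = to_bitstring(idx, L),
                      viable = as.integer(land$w > 0),
                      fitness = land$w,
                      m = genotype_robustness(land))
  if (!is.null(state)) nodes$f <- state
  if (!is.null(weights)) nodes$lambda <- weights
  size_src <- if (!is.null(weights)) weights else state
  if (!is.null(size_src)) nodes$node_size <- size_src^6
  viable_idx <- idx[land$w > 0]
  from <- integer(0); to <- integer(0)
  vset <- land$w > 0
  for (i in 0:(L - 1L)) {
    nb <- bitwXor(viable_idx, 2L^i)
    keep <- vset[nb + 1L] & nb > viable_idx
    from <- c(from, viable_idx[keep]); to <- c(to, nb[keep])
  }
  edges <- data.frame(from = to_bitstring(from, L), to = to_bitstring(to, L))
  if (!is.null(state))
    edges$width <- pmax(state[from + 1L], state[to + 1L])
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}

#' Synthetic stand-in for the empirical eight-locus A. niger landscape
#'
#' The empirical cross of two *Aspergillus niger* strains differing at 8
#' marker loci yields 2^8 = 256 possible haploid segregants of which 186
#' were isolated; the 70 missing genotypes are treated as lethal (fitness
#' 0). The measured fitness values are not public, so this generator builds
#' a synthetic landscape with the same shape: exactly 186 genotypes with
#' graded positive fitness, 70 lethal ones, and the all-zero wild type as
#' the unique fitness maximum, with fitness tending to decay with the
#' number of mutations. It is clearly labeled synthetic in its metadata and
#' is intended for protocol demonstrations, not for reproducing empirical
#' values.
#'
#' @param seed RNG seed.
#' @return a [fitness_landscape()] with `model = "aniger_standin_synthetic"`.
#' @export
make_aniger_standin <- function(seed = 1) {
  L <- 8L
  n <- 2^L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lethal <- sample(1:(n - 1L), 70)  # wild type (index 0) always viable
  d <- .popcounts(L)
  w <- 0.92^d * stats::runif(n, min = 0.80, max = 1.00)
  w[1] <- 1  # wild type: maximal fitness by construction
  w[lethal + 1L] <- 0
  fitness_landscape(w, L, model = "aniger_standin_synthetic",
                    params = list(n_viable = 186L, note = "synthetic stand-in"),
                    seed = seed)
}
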