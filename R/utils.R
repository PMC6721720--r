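# Internal helpers: node/edge vocabulary, seeded evaluation, key handling.

# Kind precedence used for canonical pair orientation in feature construction.
KIND_LEVELS <- c("miRNA", "lncRNA", "protein", "drug", "disease")

# The nine admissible association types, named "<kindA>-<kindB>" with the
# kinds in precedence order.
EDGE_KIND_PAIRS <- list(
  "miRNA-lncRNA"    = c("miRNA", "lncRNA"),
  "miRNA-disease"   = c("miRNA", "disease"),
  "miRNA-protein"   = c("miRNA", "protein"),
  "lncRNA-disease"  = c("lncRNA", "disease"),
  "lncRNA-protein"  = c("lncRNA", "protein"),
  "protein-disease" = c("protein", "disease"),
  "drug-protein"    = c("drug", "protein"),
  "drug-disease"    = c("drug", "disease"),
  "protein-protein" = c("protein", "protein")
)

#' Node kinds and association types of a molecular association network
#'
#' @return `node_kinds()` returns the five node kinds in canonical precedence
#'   order; `edge_kinds()` returns the names of the nine association types.
#' @export
node_kinds <- function() KIND_LEVELS

#' @rdname node_kinds
#' @export
edge_kinds <- function() names(EDGE_KIND_PAIRS)

# Lookup from the precedence-sorted kind pair to the association type name
# (type names follow field convention, e.g. "drug-protein", which is not
# always precedence order).
EDGE_KIND_LOOKUP <- local({
  keys <- vapply(EDGE_KIND_PAIRS, function(kp)
    paste(sort(match(kp, KIND_LEVELS)), collapse = "_"), "")
  setNames(names(EDGE_KIND_PAIRS), keys)
})

# Map an unordered kind pair to its association type name, or NA.
edge_kind_for <- function(kind_a, kind_b) {
  ra <- kind_rank(kind_a); rb <- kind_rank(kind_b)
  key <- paste(pmin(ra, rb), pmax(ra, rb), sep = "_")
  out <- EDGE_KIND_LOOKUP[key]
  unname(ifelse(is.na(ra) | is.na(rb), NA_character_, out))
}

kind_rank <- function(kind) match(kind, KIND_LEVELS)

pmin_kind <- function(a, b) ifelse(kind_rank(a) <= kind_rank(b), a, b)
pmax_kind <- function(a, b) ifelse(kind_rank(a) <= kind_rank(b), b, a)

check_kind <- function(kind) {
  bad <- setdiff(unique(kind), KIND_LEVELS)
  if (length(bad) > 0)
    stop("unknown node kind(s): ", paste(bad, collapse = ", "),
         " (must be one of ", paste(KIND_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  invisible(kind)
}

# Case-insensitive normalisation of node kinds to the canonical spelling.
normalize_kind <- function(kind) {
  idx <- match(tolower(trimws(kind)), tolower(KIND_LEVELS))
  out <- KIND_LEVELS[idx]
  if (anyNA(out))
    stop("unknown node kind(s): ",
         paste(unique(kind[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

# Identifiers are opaque strings compared after trimming and case-folding.
normalize_name <- function(name) tolower(trimws(name))

node_key <- function(kind, name) paste(kind, name, sep = ":")

split_node_key <- function(key) {
  kind <- sub(":.*$", "", key)
  name <- sub("^[^:]*:", "", key)
  data.frame(kind = kind, name = name, stringsAsFactors = FALSE)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a component seed from a top-level seed; kept well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
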