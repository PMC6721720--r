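# Disease semantics: hierarchical tree codes -> per-disease DAG ->
# decayed semantic contributions -> pairwise Jaccard-style similarity.

code_parent <- function(code) {
  p <- sub("\\.[^.]*$", "", code)
  ifelse(p == code, NA_character_, p)
}

code_depth <- function(code) lengths(strsplit(code, ".", fixed = TRUE))

#' Build the ancestor DAG of a disease from its tree codes
#'
#' Each MeSH-style tree code (dot-separated segments, e.g.
#' `C04.557.465.625.600`) denotes the disease itself; removing the last
#' segment gives the code of the parent (more abstract) disease.  The DAG
#' contains the disease's own code(s) plus the closure of all ancestors up
#' to the top-level codes, with child-to-parent edges.  A disease with
#' several tree codes gets the union DAG.
#'
#' @param tree_codes Character vector of one or more tree codes.
#' @param disease Optional disease name carried along for labelling.
#' @return An object of class `disease_dag` with components `disease`,
#'   `own_codes`, `codes` (all DAG nodes) and `edges` (data frame
#'   `child`, `parent`).
#' @export
build_disease_dag <- function(tree_codes, disease = NA_character_) {
  tree_codes <- unique(trimws(toupper(tree_codes)))
  tree_codes <- tree_codes[tree_codes != ""]
  if (length(tree_codes) == 0)
    stop("a disease needs at least one tree code", call. = FALSE)
  if (any(grepl("^\\.|\\.$|\\.\\.", tree_codes)))
    stop("malformed tree code(s): ",
         paste(tree_codes[grepl("^\\.|\\.$|\\.\\.", tree_codes)],
               collapse = ", "), call. = FALSE)
  codes <- character()
  frontier <- tree_codes
  while (length(frontier) > 0) {
    codes <- union(codes, frontier)
    frontier <- setdiff(unique(stats::na.omit(code_parent(frontier))), codes)
  }
  parents <- code_parent(codes)
  keep <- !is.na(parents)
  structure(list(disease = disease, own_codes = tree_codes,
                 codes = sort(codes),
                 edges = data.frame(child = codes[keep],
                                    parent = parents[keep],
                                    stringsAsFactors = FALSE)),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease DAG", if (!is.na(x$disease)) paste0("for '", x$disease, "'"),
      "\n  own code(s):", paste(x$own_codes, collapse = "; "),
      "\n  nodes:", length(x$codes), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Semantic contribution profile of a disease DAG
#'
#' The disease contributes 1 to itself (each of its own codes); every other
#' DAG node `t` contributes `max(delta * DD(t'))` over its children `t'`,
#' so contributions decay geometrically with distance from the disease.
#' The semantic value `DV` is the sum of all contributions.
#'
#' @param dag A `disease_dag`.
#' @param delta Semantic decay factor per level, in (0, 1); default 0.5.
#' @return An object of class `semantic_profile`: list with `DD` (named
#'   contribution vector over DAG codes), `DV` (their sum) and `delta`.
#' @examples
#' d <- build_disease_dag("C04.557.465")
#' semantic_profile(d)$DD
#' @export
semantic_profile <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  codes <- dag$codes
  DD <- setNames(rep(NA_real_, length(codes)), codes)
  DD[dag$own_codes] <- 1
  # children deeper than parents: process deepest first, so each non-own
  # code sees finished children (truncation removes exactly one segment).
  ord <- codes[order(code_depth(codes), decreasing = TRUE)]
  children_of <- split(dag$edges$child, dag$edges$parent)
  for (t in ord) {
    if (!is.na(DD[[t]])) next
    ch <- children_of[[t]]
    DD[[t]] <- delta * max(DD[ch])
  }
  if (anyNA(DD)) stop("disconnected or cyclic DAG", call. = FALSE)
  structure(list(disease = dag$disease, DD = DD, DV = sum(DD), delta = delta),
            class = "semantic_profile")
}

#' Jaccard-style semantic similarity between two diseases
#'
#' `S1(i, j)` sums, over the descriptor codes shared by the two disease
#' DAGs, the contributions of the code to each disease, normalized by the
#' sum of the two semantic values.  Symmetric, in `[0, 1]`, and 1 for a
#' disease against itself.
#'
#' @param i,j `semantic_profile` objects computed with the same `delta`.
#' @return A single similarity in `[0, 1]`.
#' @export
disease_similarity <- function(i, j) {
  stopifnot(inherits(i, "semantic_profile"), inherits(j, "semantic_profile"))
  shared <- sort(intersect(names(i$DD), names(j$DD)))
  sum(i$DD[shared] + j$DD[shared]) / (i$DV + j$DV)
}

#' Pairwise semantic similarity matrix over a set of diseases
#'
#' Vectorised evaluation of [disease_similarity()] for all pairs: with `M`
#' the descriptor-by-disease contribution matrix and `I` its nonzero
#' indicator, the numerator matrix is `t(M) I + t(I) M`.
#'
#' @param profiles Named list of `semantic_profile` objects.
#' @return A symmetric matrix with unit diagonal.
#' @export
disease_similarity_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  all_codes <- sort(unique(unlist(lapply(profiles, function(p) names(p$DD)))))
  M <- matrix(0, length(all_codes), length(profiles),
              dimnames = list(all_codes, names(profiles)))
  for (k in seq_along(profiles)) M[names(profiles[[k]]$DD), k] <- profiles[[k]]$DD
  I <- (M > 0) * 1
  num <- crossprod(M, I) + crossprod(I, M)
  DV <- vapply(profiles, `[[`, numeric(1), "DV")
  num / outer(DV, DV, `+`)
}

#' Read a disease tree-code table
#'
#' TSV with header columns `disease_name` and `tree_codes`
#' (semicolon-separated dot-notation codes).
#'
#' @param path File path.
#' @return Named list mapping case-folded disease name to a character
#'   vector of tree codes.
#' @export
read_disease_table <- function(path) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  stopifnot(all(c("disease_name", "tree_codes") %in% names(raw)))
  setNames(lapply(strsplit(raw$tree_codes, ";", fixed = TRUE), trimws),
           normalize_name(raw$disease_name))
}

#' Write a disease tree-code table
#' @param tree_codes Named list of code vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_table <- function(tree_codes, path) {
  out <- data.frame(disease_name = names(tree_codes),
                    tree_codes = vapply(tree_codes, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
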