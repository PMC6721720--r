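# Drug structure attributes: Morgan (extended-connectivity) fingerprints
# computed from SMILES with the Open Babel command-line tool, folded to a
# fixed bit length.  Molecules are fingerprinted in batches through one
# `obabel` subprocess (FPS output), which keeps the R process small no
# matter how many drugs are encoded.

ob_binary <- function() {
  path <- Sys.which("obabel")
  if (path == "")
    stop("the 'obabel' executable is required for fingerprinting but was ",
         "not found on the PATH", call. = FALSE)
  path
}

# Batch ECFP fingerprints: returns a length(smiles) x 4096 0/1 matrix with
# NA rows for molecules Open Babel could not parse.  Bits are the MSB-first
# binary expansion of the FPS hex string.
ob_fingerprints <- function(smiles, radius = 2) {
  stopifnot(radius >= 0, radius <= 5)
  n <- length(smiles)
  out <- matrix(NA_integer_, n, 4096)
  if (n == 0) return(out)
  ids <- paste0("m", seq_len(n))
  infile <- tempfile(fileext = ".smi")
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(c(infile, errfile)), add = TRUE)
  writeLines(paste(smiles, ids), infile)
  lines <- suppressWarnings(system2(
    ob_binary(), c(infile, "-ofps", paste0("-xfECFP", 2L * radius)),
    stdout = TRUE, stderr = errfile))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hex <- vapply(parts, `[`, "", 1)
  row <- match(vapply(parts, `[`, "", 2), ids)
  keep <- !is.na(row) & nchar(hex) == 1024
  if (!any(keep)) return(out)
  # nibble lookup: one row of 4 bits (MSB first) per hex character
  nibble <- matrix(0L, 16, 4)
  for (v in 0:15) nibble[v + 1, ] <- as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L))
  chars <- strsplit(toupper(hex[keep]), "", fixed = TRUE)
  vals <- match(unlist(chars), c(0:9, LETTERS[1:6])) # 1..16
  bits <- matrix(t(nibble[vals, , drop = FALSE]), nrow = sum(keep),
                 ncol = 4096, byrow = TRUE)
  out[row[keep], ] <- bits
  out
}

fold_bits <- function(bits, nbits) {
  folded <- integer(nbits)
  on_idx <- which(bits != 0)
  folded[unique((on_idx - 1L) %% nbits + 1L)] <- 1L
  folded
}

#' Morgan fingerprint of a molecule from its SMILES
#'
#' Computes the extended-connectivity circular fingerprint of the given
#' radius (ECFP with diameter `2 * radius`) via Open Babel and folds it to
#' `bits` positions by OR-ing indices modulo `bits`.
#'
#' @param smiles A single SMILES string.
#' @param bits Folded fingerprint length (default 1024).
#' @param radius Circular neighborhood radius (default 2, i.e. ECFP4).
#' @return An integer 0/1 vector of length `bits`.
#' @examples
#' sum(smiles_to_fingerprint("CC(=O)Oc1ccccc1C(=O)O"))
#' @export
smiles_to_fingerprint <- function(smiles, bits = 1024, radius = 2) {
  stopifnot(is.character(smiles), length(smiles) == 1, bits >= 1)
  raw <- ob_fingerprints(smiles, radius = radius)[1, ]
  if (anyNA(raw) || !any(raw != 0))
    stop("cannot parse SMILES '", smiles, "'", call. = FALSE)
  fold_bits(raw, bits)
}

#' Fingerprint a table of drugs, tolerating failures
#'
#' Applies the batched Open Babel fingerprinting to every entry;
#' unparseable SMILES get the all-zero fingerprint and are counted in the
#' `n_failed` attribute (with a warning naming them).
#'
#' @param smiles Named character vector (names are drug identifiers).
#' @inheritParams smiles_to_fingerprint
#' @return A drugs-by-bits 0/1 matrix with an `n_failed` attribute.
#' @export
fingerprint_matrix <- function(smiles, bits = 1024, radius = 2) {
  out <- matrix(0L, length(smiles), bits,
                dimnames = list(names(smiles), NULL))
  raw <- ob_fingerprints(unname(unlist(smiles)), radius = radius)
  bad <- apply(raw, 1, function(r) anyNA(r) || !any(r != 0))
  for (k in which(!bad)) out[k, ] <- fold_bits(raw[k, ], bits)
  if (any(bad))
    warning(sum(bad), " SMILES failed to parse (zero fingerprint): ",
            paste(head(names(smiles)[bad], 5), collapse = ", "),
            call. = FALSE)
  attr(out, "n_failed") <- sum(bad)
  out
}

#' Read / write a drug SMILES table
#'
#' TSV with header columns `drug_name` and `smiles`.
#'
#' @param path File path.
#' @return Named character vector of SMILES keyed by case-folded drug name.
#' @export
read_smiles_table <- function(path) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  stopifnot(all(c("drug_name", "smiles") %in% names(raw)))
  setNames(raw$smiles, normalize_name(raw$drug_name))
}

#' @rdname read_smiles_table
#' @param smiles Named character vector of SMILES.
#' @export
write_smiles_table <- function(smiles, path) {
  write.table(data.frame(drug_name = names(smiles), smiles = unname(smiles)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
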