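#' Construct a binary fingerprint vector
#'
#' A fingerprint is a fixed-length 0/1 vector over hashed substructure bits.
#' The Tanimoto (Jaccard) coefficient between two such vectors is the standard
#' 2D similarity measure in ligand-based virtual screening.
#'
#' @param bits Integer (or logical) vector of 0/1 values.
#' @param provenance Free-text tag recording how the bits were produced
#'   (toolkit, version, radius). Purely informational.
#' @return An object of class `"fingerprint"`: an integer 0/1 vector with
#'   attributes `n_bits` and `provenance`.
#' @examples
#' fp <- fingerprint(c(1, 1, 0, 0))
#' popcount(fp)
#' @export
fingerprint <- function(bits, provenance = "manual") {
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("fingerprint must have at least one bit")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("fingerprint bits must all be 0 or 1")
  }
  structure(bits,
    n_bits = length(bits), provenance = provenance,
    class = "fingerprint"
  )
}

#' @rdname fingerprint
#' @param x A `fingerprint`.
#' @export
popcount <- function(x) sum(unclass(x) != 0L)

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf(
    "<fingerprint: %d bits, popcount %d, provenance '%s'>\n",
    attr(x, "n_bits"), popcount(x), attr(x, "provenance")
  ))
  invisible(x)
}

#' Tanimoto (Jaccard) similarity of two binary fingerprints
#'
#' Computes `|A intersect B| / |A union B|` over the on-bits of two
#' equal-length binary vectors: 1 means identical bit patterns, 0 means
#' disjoint. The value for two all-zero vectors is undefined (0/0) and raises
#' an error rather than silently returning a number, since a fabricated
#' similarity would corrupt any downstream encoding.
#'
#' @param a,b Binary vectors (`fingerprint` objects or plain 0/1 vectors) of
#'   equal length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(unclass(a))
  b <- as.integer(unclass(b))
  if (length(a) != length(b)) {
    stop(sprintf(
      "fingerprint length mismatch: %d vs %d bits",
      length(a), length(b)
    ))
  }
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) {
    stop("fingerprint bits must all be 0 or 1")
  }
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0L) {
    stop("Tanimoto similarity undefined: both fingerprints are all-zero (0/0)")
  }
  inter / union
}

# One python subprocess computes fingerprints for several SMILES at once
# (the toolkit import dominates runtime). Output: one line per molecule with
# space-separated on-bit positions (0-based), or PARSE_ERROR:<smiles>.
rdkit_onbits <- function(smiles, radius, n_bits) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "from rdkit.Chem import rdFingerprintGenerator",
    "radius = int(sys.argv[1]); n_bits = int(sys.argv[2])",
    "gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)",
    "for smi in sys.argv[3:]:",
    "    mol = Chem.MolFromSmiles(smi)",
    "    if mol is None:",
    "        print('PARSE_ERROR:' + smi)",
    "    else:",
    "        fp = gen.GetFingerprint(mol)",
    "        print(' '.join(str(i) for i in fp.GetOnBits()))",
    sep = "\n"
  )
  out <- suppressWarnings(system2("python",
    args = c("-c", shQuote(script), radius, n_bits, shQuote(smiles)),
    stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("fingerprint toolkit call failed (python/rdkit not available?)")
  }
  if (length(out) != length(smiles)) {
    stop("fingerprint toolkit returned unexpected output")
  }
  bad <- grep("^PARSE_ERROR:", out, value = TRUE)
  if (length(bad)) {
    stop(
      "unparseable SMILES: ",
      paste(sub("^PARSE_ERROR:", "", bad), collapse = ", ")
    )
  }
  lapply(out[seq_along(smiles)], function(line) {
    if (!nzchar(trimws(line))) integer(0) else
      as.integer(strsplit(trimws(line), "\\s+")[[1]])
  })
}

#' Morgan (ECFP-style) fingerprint of a SMILES string
#'
#' Hashes circular atom neighborhoods up to `radius` bonds into a fixed-length
#' bit vector, via a pluggable chemistry-toolkit adapter (the bundled adapter
#' shells out to the rdkit toolkit through `python`). Deterministic for a fixed
#' toolkit version and parameters.
#'
#' @param smiles A SMILES string (e.g. `"CCCC"` for butane).
#' @param radius Neighborhood radius in bonds; default 2 (ECFP4-equivalent).
#' @param n_bits Folded fingerprint length; default 2048.
#' @return A [fingerprint()] with toolkit/radius provenance.
#' @seealso [similarity_from_pair()] for the SMILES-pair convenience wrapper.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (radius < 0L) stop("radius must be >= 0")
  if (n_bits < 1L) stop("n_bits must be >= 1")
  on <- rdkit_onbits(smiles, radius, n_bits)[[1]]
  bits <- integer(n_bits)
  bits[on + 1L] <- 1L
  fingerprint(bits, provenance = sprintf(
    "rdkit-morgan radius=%d n_bits=%d", radius, n_bits
  ))
}

#' Tanimoto similarity record for a pair of molecules
#'
#' Composes [morgan_fingerprint()] and [tanimoto()] for two SMILES strings and
#' returns a similarity record carrying the value, the pair and provenance.
#' Alternatively a pre-computed similarity can be wrapped with
#' `direct_similarity()`, so the quantum layers are usable without any
#' chemistry toolkit.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @param label Free-text pair label (defaults to `"a-b"` from the SMILES).
#' @param radius,n_bits Fingerprint parameters, see [morgan_fingerprint()].
#' @return An object of class `"similarity_record"`: a list with `t_value`,
#'   `label`, `method`, `radius`, `n_bits`.
#' @examples
#' direct_similarity(0.5, label = "t=0.5")
#' @export
similarity_from_pair <- function(smiles_a, smiles_b, label = NULL,
                                 radius = 2L, n_bits = 2048L) {
  stopifnot(
    is.character(smiles_a), nzchar(smiles_a),
    is.character(smiles_b), nzchar(smiles_b)
  )
  on <- rdkit_onbits(c(smiles_a, smiles_b), radius, n_bits)
  mk <- function(pos) {
    bits <- integer(n_bits)
    bits[pos + 1L] <- 1L
    fingerprint(bits, sprintf("rdkit-morgan radius=%d n_bits=%d", radius, n_bits))
  }
  fa <- mk(on[[1]])
  fb <- mk(on[[2]])
  structure(
    list(
      t_value = tanimoto(fa, fb),
      label = label %||% paste(smiles_a, smiles_b, sep = "-"),
      method = "morgan_tanimoto",
      radius = as.integer(radius), n_bits = as.integer(n_bits),
      smiles = c(smiles_a, smiles_b)
    ),
    class = "similarity_record"
  )
}

#' @rdname similarity_from_pair
#' @param t A pre-computed similarity value in `[0, 1]`.
#' @export
direct_similarity <- function(t, label = "direct") {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0 || t > 1) stop("similarity must lie in [0, 1], got ", t)
  structure(
    list(
      t_value = as.numeric(t), label = label, method = "direct",
      radius = NA_integer_, n_bits = NA_integer_, smiles = NULL
    ),
    class = "similarity_record"
  )
}

#' @export
print.similarity_record <- function(x, ...) {
  cat(sprintf(
    "Tanimoto similarity record\n  pair:   %s\n  method: %s\n  T:      %.6g\n",
    x$label, x$method, x$t_value
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
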