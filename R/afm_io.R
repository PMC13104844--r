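# Readers for AlphaFold-Multimer / ColabFold prediction artifacts and the
# internal containers they populate.  All downstream scoring operates on the
# two types defined here: a `complex_model` (per-residue representative
# coordinates + pLDDT) and a `score_bundle` (full PAE matrix + global
# confidences).

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Construct a parsed two-chain complex model
#'
#' Container for a predicted dimer: one representative coordinate per residue
#' (the C-beta atom; C-alpha for glycine or when C-beta is absent), the
#' per-residue pLDDT read from the B-factor column, and the chain layout.
#'
#' @param pair_id Identifier of the protein pair.
#' @param rank Model rank (1..5).
#' @param chain_ids Character vector of chain identifiers (length 1 or 2).
#' @param sequences Character vector of one-letter amino-acid sequences, one
#'   per chain, same order as `chain_ids`.
#' @param coords Numeric matrix (total residues x 3) of representative
#'   coordinates in Angstrom, concatenated chain order.
#' @param plddt Numeric vector of per-residue pLDDT in \[0, 100\].
#' @return An object of class `complex_model` with fields `pair_id`, `rank`,
#'   `chain_ids`, `sequences`, `coords`, `plddt`, `chain_offsets` (0-based
#'   start of each chain in the concatenated order) and `chain_lengths`.
#' @export
complex_model <- function(pair_id, rank, chain_ids, sequences, coords, plddt) {
  chain_lengths <- nchar(sequences)
  n <- sum(chain_lengths)
  if (nrow(coords) != n)
    stop("coordinate count (", nrow(coords), ") does not match total sequence length (", n, ")")
  if (length(plddt) != n)
    stop("pLDDT length does not match total residue count")
  if (any(plddt < 0 | plddt > 100))
    stop("pLDDT values must lie in [0, 100]")
  if (length(chain_ids) != length(sequences))
    stop("chain_ids and sequences differ in length")
  structure(list(
    pair_id = pair_id,
    rank = as.integer(rank),
    chain_ids = chain_ids,
    sequences = sequences,
    coords = coords,
    plddt = as.numeric(plddt),
    chain_offsets = c(0L, cumsum(chain_lengths))[seq_along(chain_ids)],
    chain_lengths = as.integer(chain_lengths)
  ), class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model> pair ", x$pair_id, ", rank ", x$rank, "\n", sep = "")
  for (k in seq_along(x$chain_ids))
    cat("  chain ", x$chain_ids[k], ": ", x$chain_lengths[k], " residues\n", sep = "")
  invisible(x)
}

# 1-based residue indices of chain k in the concatenated order
chain_index <- function(model, k) {
  seq.int(model$chain_offsets[k] + 1L, model$chain_offsets[k] + model$chain_lengths[k])
}

#' Construct a score bundle (PAE matrix + global confidences)
#'
#' @param pair_id Pair identifier.
#' @param rank Model rank.
#' @param pae Square numeric matrix of predicted aligned errors in Angstrom.
#'   Stored as emitted (possibly asymmetric); row i / column j is the expected
#'   error of residue j when the model is aligned on residue i's frame.
#' @param ptm,iptm Global predicted TM-scores in \[0, 1\].
#' @param plddt Per-residue pLDDT vector.
#' @return Object of class `score_bundle`.
#' @export
score_bundle <- function(pair_id, rank, pae, ptm, iptm, plddt) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square")
  if (any(pae < 0)) stop("PAE entries must be nonnegative")
  if (length(plddt) && length(plddt) != nrow(pae))
    stop("plddt length does not match PAE dimension")
  for (v in c(ptm = ptm, iptm = iptm))
    if (!is.na(v) && (v < 0 || v > 1)) stop("ptm/iptm must lie in [0, 1]")
  structure(list(pair_id = pair_id, rank = as.integer(rank), pae = pae,
                 ptm = as.numeric(ptm), iptm = as.numeric(iptm),
                 plddt = as.numeric(plddt)),
            class = "score_bundle")
}

#' @export
print.score_bundle <- function(x, ...) {
  cat("<score_bundle> pair ", x$pair_id, ", rank ", x$rank,
      ", ", nrow(x$pae), "x", ncol(x$pae), " PAE, ipTM ", x$iptm, "\n", sep = "")
  invisible(x)
}

#' Read a predicted structure into a complex model
#'
#' Parses a PDB or mmCIF coordinate file and reduces every standard
#' amino-acid residue to one representative coordinate: the C-beta atom, or
#' the C-alpha when no C-beta exists (always for glycine).  The per-residue
#' pLDDT is taken from the B-factor of the representative atom, the AFM
#' convention.
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @return A [complex_model()].  Files with more than two chains are rejected:
#'   all scoring in this package is defined on dimers (a homodimer is two
#'   identical chains).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_atoms(path) else parse_mmcif_atoms(path)
  atoms <- atoms[atoms$resname %in% names(AA3TO1), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no standard amino-acid ATOM records parsed from ", path)

  chains <- unique(atoms$chain)
  if (length(chains) > 2)
    stop("file has ", length(chains), " chains; only dimers (<= 2 chains) are supported")

  sequences <- character(0); coords <- NULL; plddt <- numeric(0)
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    # residues in file order
    key <- paste(a$resseq, a$icode)
    res_keys <- unique(key)
    seq_ch <- character(length(res_keys))
    xyz <- matrix(NA_real_, length(res_keys), 3)
    b <- numeric(length(res_keys))
    for (r in seq_along(res_keys)) {
      ra <- a[key == res_keys[r], , drop = FALSE]
      seq_ch[r] <- AA3TO1[[ra$resname[1]]]
      rep_row <- match("CB", ra$name)
      if (is.na(rep_row)) rep_row <- match("CA", ra$name)
      if (is.na(rep_row))
        stop("residue ", ra$resname[1], " ", ra$resseq[1], " in chain ", ch,
             " has neither CB nor CA atom")
      xyz[r, ] <- c(ra$x[rep_row], ra$y[rep_row], ra$z[rep_row])
      b[r] <- ra$bfac[rep_row]
    }
    sequences <- c(sequences, paste(seq_ch, collapse = ""))
    coords <- rbind(coords, xyz)
    plddt <- c(plddt, b)
  }
  pair_id <- sub("_(un)?relaxed.*$", "",
                 sub("\\.(pdb|cif|mmcif)$", "", basename(path)))
  complex_model(pair_id, rank = guess_rank(path), chain_ids = chains,
                sequences = sequences, coords = coords, plddt = plddt)
}

guess_rank <- function(path) {
  m <- regmatches(basename(path), regexpr("rank_0*([0-9]+)", basename(path)))
  if (length(m) == 0) return(1L)
  as.integer(sub("rank_0*", "", m))
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0) stop("no ATOM records in ", path, " (unparseable as PDB)")
  df <- data.frame(
    name    = trimws(substr(lines, 13, 16)),
    altloc  = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resseq  = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode   = substr(lines, 27, 27),
    x = suppressWarnings(as.numeric(substr(lines, 31, 38))),
    y = suppressWarnings(as.numeric(substr(lines, 39, 46))),
    z = suppressWarnings(as.numeric(substr(lines, 47, 54))),
    bfac = suppressWarnings(as.numeric(substr(lines, 61, 66))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) || anyNA(df$resseq))
    stop("malformed ATOM record in ", path)
  df[df$altloc %in% c(" ", "A", ""), , drop = FALSE]
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0) stop("no _atom_site loop in ", path, " (unparseable as mmCIF)")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  body <- character(0)
  for (i in seq(body_start, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") || startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  if (length(body) == 0) stop("empty _atom_site loop in ", path)
  toks <- strsplit(body, "[[:space:]]+")
  if (any(lengths(toks) != length(tags))) stop("ragged _atom_site rows in ", path)
  tab <- do.call(rbind, toks)
  colnames(tab) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(tab[, nm])
    stop("mmCIF file lacks required atom_site field: ", paste(c(...), collapse = "/"))
  }
  grp <- if ("group_PDB" %in% tags) tab[, "group_PDB"] else rep("ATOM", nrow(tab))
  df <- data.frame(
    name    = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
    altloc  = if ("label_alt_id" %in% tags) tab[, "label_alt_id"] else ".",
    resname = pick("auth_comp_id", "label_comp_id"),
    chain   = pick("auth_asym_id", "label_asym_id"),
    resseq  = as.integer(pick("auth_seq_id", "label_seq_id")),
    icode   = ".",
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    bfac = as.numeric(pick("B_iso_or_equiv")),
    stringsAsFactors = FALSE
  )
  df <- df[grp == "ATOM", , drop = FALSE]
  df[df$altloc %in% c(".", "A", "?"), , drop = FALSE]
}

#' Read a ColabFold score JSON into a score bundle
#'
#' Accepts the ColabFold per-rank dialect (`*_scores_rank_00N*.json`) and the
#' plain fixture dialect: a JSON object with keys `pae` (square matrix),
#' `plddt` (vector), `ptm` and `iptm`.  The PAE matrix is stored exactly as
#' read; no symmetrization happens at read time.
#'
#' @param path Path to the JSON score file.
#' @param pair_id Optional pair identifier; defaults to the file stem.
#' @return A [score_bundle()].
#' @export
read_scores <- function(path, pair_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj[["pae"]]))
    stop("score JSON lacks a 'pae' key: ", path)
  if (is.list(obj[["pae"]]) && length(unique(lengths(obj[["pae"]]))) > 1)
    stop("ragged PAE matrix in ", path)
  pae <- if (is.list(obj[["pae"]])) do.call(rbind, obj[["pae"]]) else as.matrix(obj[["pae"]])
  if (nrow(pae) != ncol(pae)) stop("PAE matrix in ", path, " is not square")
  iptm <- obj[["iptm"]]   # exact: `$` would partial-match "iptm+ptm"
  if (is.null(iptm)) {
    if (!is.null(obj[["iptm+ptm"]]))
      stop("score JSON carries only the combined 'iptm+ptm' ranking score; ",
           "this reader supports the ColabFold per-rank dialect with separate ",
           "'iptm' and 'ptm' keys")
    iptm <- NA_real_
  }
  if (is.null(pair_id))
    pair_id <- sub("_scores.*$", "", sub("\\.json$", "", basename(path)))
  score_bundle(pair_id, rank = guess_rank(path), pae = pae,
               ptm = if (is.null(obj[["ptm"]])) NA_real_ else obj[["ptm"]],
               iptm = iptm,
               plddt = if (is.null(obj[["plddt"]])) numeric(0)
                       else as.numeric(obj[["plddt"]]))
}

#' Inter-chain contact map at a C-beta distance cutoff
#'
#' @param model A two-chain [complex_model()].
#' @param cutoff Distance cutoff in Angstrom; the boundary is inclusive
#'   (`<= cutoff`), default 8.
#' @return Logical matrix (chain-A residues x chain-B residues); entry (i, j)
#'   is `TRUE` iff the representative-coordinate distance is at most `cutoff`.
#' @export
contact_map <- function(model, cutoff = 8) {
  if (length(model$chain_ids) != 2)
    stop("contact_map requires a two-chain model")
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- model$coords[chain_index(model, 1), , drop = FALSE]
  b <- model$coords[chain_index(model, 2), , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # numerical guard
  d2 <= cutoff^2
}

#' Assemble a prediction set from per-rank model/score files
#'
#' Discovers files named `<pair>*rank_00N*` in a directory and pairs each
#' coordinate file with its score JSON by rank.
#'
#' @param dir Directory holding the prediction artifacts.
#' @param pair_id Pair identifier used as the filename prefix.
#' @return A list of class `prediction_set` with elements `pair_id` and
#'   `models`, a rank-ordered list of `list(model =, scores =)`.
#' @export
read_prediction_set <- function(dir, pair_id) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[startsWith(basename(files), pair_id)]
  struct <- files[grepl("\\.(pdb|cif|mmcif)$", files)]
  scores <- files[grepl("\\.json$", files) & grepl("scores", basename(files))]
  ranks_s <- vapply(struct, guess_rank, integer(1))
  ranks_j <- vapply(scores, guess_rank, integer(1))
  if (anyDuplicated(ranks_s) || anyDuplicated(ranks_j))
    stop("duplicate rank among prediction files for pair ", pair_id)
  common <- sort(intersect(ranks_s, ranks_j))
  if (length(common) == 0) stop("no matched model/score file pairs for ", pair_id)
  models <- lapply(common, function(r) {
    m <- read_structure(struct[ranks_s == r])
    s <- read_scores(scores[ranks_j == r], pair_id = pair_id)
    m$pair_id <- pair_id
    m$rank <- s$rank <- as.integer(r)
    list(model = m, scores = s)
  })
  first_seq <- models[[1]]$model$sequences
  for (m in models)
    if (!identical(m$model$sequences, first_seq))
      stop("models of pair ", pair_id, " differ in sequence")
  structure(list(pair_id = pair_id, models = models), class = "prediction_set")
}

#' Write a complex model as a minimal PDB file
#'
#' Emits CA and CB ATOM records (CA only for glycine) with the pLDDT in the
#' B-factor column; the inverse of [read_structure()] for fixture round-trips.
#'
#' @param model A [complex_model()].  The CA record reuses the representative
#'   coordinate; geometry beyond the representative atom is not reconstructed.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (k in seq_along(model$chain_ids)) {
    idx <- chain_index(model, k)
    aas <- strsplit(model$sequences[k], "")[[1]]
    for (r in seq_along(idx)) {
      i <- idx[r]
      res3 <- AA1TO3[[aas[r]]]
      emit <- function(atom) {
        serial <<- serial + 1L
        cat(sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f\n",
                    serial, atom, res3, model$chain_ids[k], r,
                    model$coords[i, 1], model$coords[i, 2], model$coords[i, 3],
                    1.00, model$plddt[i]), file = con)
      }
      emit("CA")
      if (aas[r] != "G") emit("CB")
    }
    cat("TER\n", file = con)
  }
  cat("END\n", file = con)
  invisible(path)
}

#' Write a score bundle as a fixture-dialect JSON
#'
#' @param scores A [score_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_json <- function(scores, path) {
  obj <- list(pae = scores$pae, plddt = scores$plddt,
              ptm = scores$ptm, iptm = scores$iptm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
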