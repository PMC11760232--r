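IUPAC_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Character-validity policy for one-hot encoding
#'
#' Controls which residues become bit-columns. `"nucleotide"` accepts
#' A/T/C/G/U case-insensitively; `"protein"` the 20 unambiguous IUPAC amino
#' acid letters case-insensitively; `"molecular"` their union (mixed data);
#' `"default"` accepts every letter (case-sensitive) and digit, which admits
#' arbitrary coded characters (methylation states, gene presence/absence, ...).
#' The gap `-` and missing `?` characters are never valid, and in the three
#' molecular modes ambiguity codes (N, X, B, Z, J, ...) are treated as missing
#' data.
#'
#' @param mode One of `"default"`, `"nucleotide"`, `"protein"`, `"molecular"`.
#' @return A `data_type_policy` list with the valid-character set and case flag.
#' @export
data_type_policy <- function(mode = c("default", "nucleotide", "protein", "molecular")) {
  mode <- match.arg(mode)
  valid <- switch(mode,
    nucleotide = c("A", "T", "C", "G", "U"),
    protein    = IUPAC_AA,
    molecular  = sort(unique(c(IUPAC_AA, "U"))),
    default    = c(LETTERS, letters, as.character(0:9))
  )
  structure(list(mode = mode, valid = valid,
                 case_sensitive = (mode == "default")),
            class = "data_type_policy")
}

# Map raw alignment characters to canonical states; invalid -> NA.
normalize_chars <- function(x, policy) {
  if (!policy$case_sensitive) x <- toupper(x)
  x[!(x %in% policy$valid)] <- NA_character_
  x
}

#' Read one aligned FASTA file as a feature group
#'
#' Each FASTA file is one group (typically a gene); the file stem is the group
#' name. Sequence descriptions after the first whitespace are dropped.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `alignment_group`: `list(name, seqs)` with `seqs` a named
#'   character vector of equal-length aligned sequences.
#' @export
read_fasta_group <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop2("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(ss) == 0L) stop2("FASTA file is empty: ", path)
  if (length(ss) < 2L) stop2("alignment '", path, "' has fewer than 2 sequences")
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop2("duplicate sequence name(s) in '", path, "': ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    stop2("unequal sequence lengths in alignment '", path, "' (",
          paste(sort(unique(w)), collapse = ", "), ")")
  }
  seqs <- stats::setNames(as.character(ss), nm)
  structure(list(name = file_stem(path), seqs = seqs), class = "alignment_group")
}

#' Read a directory (or file list) of FASTA groups
#'
#' @param paths A directory containing `.fa`/`.fasta`/`.fas`/`.txt` files, or a
#'   character vector of FASTA paths (order defines group/column order).
#' @return Named list of `alignment_group`s.
#' @export
read_alignment_groups <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta|fas|txt)$",
                        full.names = TRUE)
    paths <- sort(paths)
  }
  if (length(paths) == 0L) stop2("no alignment files found")
  groups <- lapply(paths, read_fasta_group)
  nms <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nms)) stop2("duplicate group names: ",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  stats::setNames(groups, nms)
}

new_bit_matrix <- function(X, taxa, features, group_lengths) {
  rownames(X) <- NULL
  structure(list(X = X, taxa = taxa, features = features,
                 group_lengths = group_lengths),
            class = "bit_matrix")
}

#' @export
print.bit_matrix <- function(x, ...) {
  cat(sprintf("<bit_matrix: %d taxa x %d bit-columns, %d group(s)>\n",
              length(x$taxa), nrow(x$features), length(x$group_lengths)))
  invisible(x)
}

# Encode one group over the unique taxa; returns feature df + triplets.
encode_group <- function(g, utaxa, policy) {
  L <- nchar(g$seqs[[1]])
  present <- intersect(utaxa, names(g$seqs))
  if (length(present) == 0L || L == 0L) {
    return(list(features = data.frame(group = character(0), pos = integer(0),
                                      state = character(0), pos_valid = integer(0),
                                      stringsAsFactors = FALSE),
                i = integer(0), j = integer(0)))
  }
  chars <- matrix(unlist(strsplit(g$seqs[present], "", fixed = TRUE), use.names = FALSE),
                  nrow = length(present), byrow = TRUE)
  chars <- matrix(normalize_chars(chars, policy), nrow = length(present))
  hit <- which(!is.na(chars), arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(list(features = data.frame(group = character(0), pos = integer(0),
                                      state = character(0), pos_valid = integer(0),
                                      stringsAsFactors = FALSE),
                i = integer(0), j = integer(0)))
  }
  pos <- hit[, 2L]
  state <- chars[hit]
  row_taxon <- match(present[hit[, 1L]], utaxa)
  # one bit-column per distinct (position, state); ASCII state order within pos
  key <- paste(pos, state, sep = "\r")
  ukey <- unique(key)
  upos <- as.integer(sub("\r.*", "", ukey))
  ustate <- sub(".*\r", "", ukey)
  ord <- order(upos, ustate, method = "radix")
  ukey <- ukey[ord]; upos <- upos[ord]; ustate <- ustate[ord]
  j <- match(key, ukey)
  pv <- as.integer(table(factor(pos, levels = sort(unique(upos)))))
  pos_valid <- stats::setNames(pv, sort(unique(upos)))[as.character(upos)]
  list(features = data.frame(group = g$name, pos = upos, state = ustate,
                             pos_valid = as.integer(pos_valid),
                             stringsAsFactors = FALSE),
       i = row_taxon, j = j)
}

#' One-hot encode grouped alignments into a bit matrix
#'
#' Every alignment position becomes one binary column per distinct valid
#' character state observed at that position among the selected taxa; gaps,
#' `?`, and characters outside the policy's valid set contribute nothing.
#' Taxa absent from a group get 0 in all of that group's columns; taxa present
#' in an alignment but not in `taxa` are dropped with a warning.
#'
#' @param groups List of `alignment_group`s (order fixes column-block order).
#' @param taxa Ordered taxon vector (the rows; duplicates allowed to support
#'   up-sampled class maps).
#' @param policy A [data_type_policy()].
#' @return A `bit_matrix`: sparse 0/1 matrix plus per-column metadata
#'   (`group`, `pos`, `state`, `pos_valid` = number of distinct taxa with a
#'   valid state at the position) and per-group alignment lengths.
#' @export
one_hot_encode <- function(groups, taxa, policy = data_type_policy()) {
  stopifnot(length(taxa) > 0L)
  utaxa <- unique(taxa)
  aln_taxa <- unique(unlist(lapply(groups, function(g) names(g$seqs))))
  extra <- setdiff(aln_taxa, utaxa)
  if (length(extra) > 0L) {
    warn2(length(extra), " taxon/taxa present in alignments but absent from the ",
          "class map were dropped: ", paste(utils::head(extra, 5), collapse = ", "),
          if (length(extra) > 5L) ", ..." else "")
  }
  parts <- lapply(groups, encode_group, utaxa = utaxa, policy = policy)
  nfeat <- vapply(parts, function(p) nrow(p$features), integer(1))
  offsets <- cumsum(c(0L, utils::head(nfeat, -1L)))
  i <- unlist(lapply(parts, `[[`, "i"), use.names = FALSE)
  j <- unlist(mapply(function(p, off) p$j + off, parts, offsets,
                     SIMPLIFY = FALSE), use.names = FALSE)
  features <- do.call(rbind, lapply(parts, `[[`, "features"))
  rownames(features) <- NULL
  features$id <- paste(features$group, features$pos, features$state, sep = "|")
  Xu <- Matrix::sparseMatrix(i = i %||% integer(0), j = j %||% integer(0), x = 1,
                             dims = c(length(utaxa), sum(nfeat)))
  X <- Xu[match(taxa, utaxa), , drop = FALSE]
  gl <- vapply(groups, function(g) nchar(g$seqs[[1]]), integer(1))
  names(gl) <- vapply(groups, `[[`, "", "name")
  new_bit_matrix(X, taxa, features, gl)
}

#' Restrict a bit matrix to a subset of rows
#'
#' Recomputes per-position valid-row counts for the subset so that
#' [filter_bits()] applied afterwards reflects the retained taxa only (as
#' required when re-deriving filters inside a cross-validation training fold).
#'
#' @param m A `bit_matrix`.
#' @param rows Integer row indices to keep.
#' @return A `bit_matrix` over `taxa[rows]`.
#' @export
subset_taxa <- function(m, rows) {
  X <- m$X[rows, , drop = FALSE]
  feats <- m$features
  ones <- Matrix::colSums(X)
  key <- paste(feats$group, feats$pos, sep = "\r")
  feats$pos_valid <- as.integer(stats::ave(ones, key, FUN = sum))
  new_bit_matrix(X, m$taxa[rows], feats, m$group_lengths)
}

#' Remove uninformative bit-columns
#'
#' Applies, in order: (1) monomorphic columns — every row with a valid state
#' at the position carries this state, so the column equals the position's
#' valid-row indicator; (2) singleton columns — exactly one row carries a 1;
#' (3) low-count columns — fewer than `bit_ct` ones, when `bit_ct > 0`.
#' Columns that lost every carrier to a row subset are removed as `"empty"`.
#' The monomorphic test uses the valid-row count recorded on the matrix, so
#' filtering is idempotent.
#'
#' @param m A `bit_matrix`.
#' @param bit_ct Minimum number of 1s a column must have (0 disables).
#' @return The filtered `bit_matrix`, with attributes `removal_log` (data frame
#'   `id`, `reason`) and `removal_counts` (named integer vector including
#'   `kept`).
#' @export
filter_bits <- function(m, bit_ct = 0L) {
  stopifnot(inherits(m, "bit_matrix"), bit_ct >= 0L)
  ones <- Matrix::colSums(m$X)
  pv <- m$features$pos_valid
  reason <- rep(NA_character_, length(ones))
  reason[ones == 0] <- "empty"
  reason[is.na(reason) & ones == pv] <- "monomorphic"
  reason[is.na(reason) & ones == 1] <- "singleton"
  if (bit_ct > 0L) reason[is.na(reason) & ones < bit_ct] <- "bit_ct"
  keep <- is.na(reason)
  out <- new_bit_matrix(m$X[, keep, drop = FALSE], m$taxa,
                        m$features[keep, , drop = FALSE], m$group_lengths)
  rownames(out$features) <- NULL
  log <- data.frame(id = m$features$id[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  counts <- c(kept = sum(keep),
              monomorphic = sum(reason == "monomorphic", na.rm = TRUE),
              singleton = sum(reason == "singleton", na.rm = TRUE),
              bit_ct = sum(reason == "bit_ct", na.rm = TRUE),
              empty = sum(reason == "empty", na.rm = TRUE))
  attr(out, "removal_log") <- log
  attr(out, "removal_counts") <- counts
  out
}
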