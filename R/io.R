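# Alignment containers and readers/writers for FASTA, NEXUS (DATA + SETS
# blocks) and Newick. All serialized coordinates are 1-based inclusive.

IUPAC_CODES <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 15L,
                 `?` = 15L)

validate_alignment <- function(aln) {
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix (taxa x sites)")
  if (is.null(rownames(aln)) || any(!nzchar(rownames(aln))))
    stop("alignment rows must be named with taxon labels")
  dup <- rownames(aln)[duplicated(rownames(aln))]
  if (length(dup))
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(as.vector(aln)), names(IUPAC_CODES))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  invisible(aln)
}

#' Encode an alignment as IUPAC bitmasks
#'
#' Internal representation used by the likelihood and parsimony engines:
#' integers with bits A=1, C=2, G=4, T=8; gaps, `?` and `N` become 15
#' (fully missing).
#'
#' @param aln character matrix (taxa x sites) with taxon rownames.
#' @return Integer matrix of the same shape.
#' @keywords internal
encode_alignment <- function(aln) {
  validate_alignment(aln)
  enc <- IUPAC_CODES[aln]
  dim(enc) <- dim(aln)
  rownames(enc) <- rownames(aln)
  enc
}

# collapse identical site columns; returns patterns (ntaxa x npat),
# weights and site -> pattern index
compress_patterns <- function(enc) {
  key <- do.call(paste, c(as.data.frame(t(enc)), sep = ","))
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(patterns = enc[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(u))),
       index = idx)
}

#' Read and write FASTA alignments
#'
#' Sequences are uppercased on input; `U` is read as `T`. All rows must have
#' equal length (ragged input is rejected with a per-taxon length report) and
#' taxon labels must be unique.
#'
#' @param path file path.
#' @return [read_fasta()] returns a character matrix (taxa x sites) with
#'   taxon rownames; [write_fasta()] returns `path` invisibly.
#' @export
#' @examples
#' aln <- matrix(c("A","C","G","T","A","C","A","T"), 2, 4,
#'               dimnames = list(c("t1","t2"), NULL))
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(aln, f)
#' identical(read_fasta(f), aln)
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers in ", path)
  labels <- trimws(sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- character(length(hdr))
  for (i in seq_along(hdr)) {
    body <- lines[seq(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    seqs[i] <- toupper(gsub("[[:space:]]", "", paste(body, collapse = "")))
  }
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged FASTA rows: ",
         paste(sprintf("%s=%d", labels, lens), collapse = ", "))
  aln <- matrix(unlist(strsplit(seqs, "")), nrow = length(labels),
                byrow = TRUE, dimnames = list(labels, NULL))
  aln[aln == "U"] <- "T"
  validate_alignment(aln)
  aln
}

#' @rdname read_fasta
#' @param aln character alignment matrix with taxon rownames.
#' @param width line-wrap width for sequence lines.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  validate_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Partitioned alignments
#'
#' Couples an alignment with named, disjoint gene partitions (charsets).
#' Internally a partition is a sorted vector of 1-based site indices; on disk
#' (NEXUS `charset`) partitions are 1-based inclusive ranges.
#'
#' @param aln character alignment matrix with taxon rownames.
#' @param parts named list of integer site-index vectors, or a data.frame
#'   with columns `gene`, `start`, `end`.
#' @return An object of class `partitioned_alignment` with elements `seq`
#'   and `parts`.
#' @export
partitioned_alignment <- function(aln, parts) {
  validate_alignment(aln)
  if (is.data.frame(parts)) {
    parts <- setNames(
      mapply(function(s, e) seq.int(s, e), parts$start, parts$end,
             SIMPLIFY = FALSE),
      parts$gene)
  }
  if (is.null(names(parts)) || any(!nzchar(names(parts))))
    stop("partitions must be named")
  parts <- lapply(parts, function(ix) sort(unique(as.integer(ix))))
  all_ix <- unlist(parts, use.names = FALSE)
  if (anyDuplicated(all_ix))
    stop("overlapping partitions: a site belongs to more than one charset")
  if (length(all_ix) && (min(all_ix) < 1L || max(all_ix) > ncol(aln)))
    stop("charset exceeds matrix length (", ncol(aln), " sites)")
  structure(list(seq = aln, parts = parts), class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat("Partitioned alignment:", nrow(x$seq), "taxa x", ncol(x$seq),
      "sites,", length(x$parts), "partitions\n")
  w <- vapply(x$parts, length, 1L)
  cat(paste(sprintf("%s(%d)", names(w), w), collapse = " "), "\n")
  invisible(x)
}

#' Extract and concatenate gene partitions
#'
#' Returns the column-concatenation of the named genes in partition order
#' (the order of `pa$parts`), used for single-gene matrices, functional
#' category matrices and leave-one-out "antigene" matrices.
#'
#' @param pa a [partitioned_alignment].
#' @param genes character vector of partition names to keep.
#' @return Character alignment matrix.
#' @export
extract_partition <- function(pa, genes) {
  stopifnot(inherits(pa, "partitioned_alignment"))
  unknown <- setdiff(genes, names(pa$parts))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  keep <- names(pa$parts)[names(pa$parts) %in% genes]
  idx <- unlist(pa$parts[keep], use.names = FALSE)
  pa$seq[, idx, drop = FALSE]
}

#' Restrict a partitioned alignment to a subset of genes
#'
#' Keeps the named partitions (in the alignment's own order), drops all other
#' columns and renumbers the partitions contiguously.
#'
#' @param pa a [partitioned_alignment].
#' @param genes partition names to retain.
#' @return A [partitioned_alignment] over the retained genes.
#' @export
subset_genes <- function(pa, genes) {
  stopifnot(inherits(pa, "partitioned_alignment"))
  unknown <- setdiff(genes, names(pa$parts))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  keep <- names(pa$parts)[names(pa$parts) %in% genes]
  idx <- unlist(pa$parts[keep], use.names = FALSE)
  w <- lengths(pa$parts[keep])
  ends <- cumsum(w)
  parts <- Map(function(a, b) seq.int(a, b), ends - w + 1L, ends)
  partitioned_alignment(pa$seq[, idx, drop = FALSE], setNames(parts, keep))
}

# collapse sorted indices to "a-b c-d" range syntax
ranges_of <- function(ix) {
  br <- c(0L, which(diff(ix) != 1L), length(ix))
  paste(vapply(seq_len(length(br) - 1L), function(k) {
    a <- ix[br[k] + 1L]; b <- ix[br[k + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, ""), collapse = " ")
}

#' Read and write NEXUS alignments with charsets
#'
#' Parses the DATA block (sequential or interleaved MATRIX, one labelled
#' line per taxon per block) and an optional SETS block of
#' `charset <gene> = <start>-<end>;` declarations, 1-based inclusive.
#' A missing SETS block yields a single partition named `"all"`.
#' Overlapping charsets and charsets beyond the matrix length are rejected.
#'
#' @param path file path.
#' @return [read_nexus()] returns a [partitioned_alignment];
#'   [write_nexus()] returns `path` invisibly.
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)   # strip comments
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file: ", path)
  # MATRIX section of the DATA (or CHARACTERS) block
  m <- regmatches(txt, regexpr("(?is)matrix(.*?);", txt, perl = TRUE))
  if (!length(m)) stop("no MATRIX command found in ", path)
  body <- sub("(?is)^matrix", "", m, perl = TRUE)
  body <- sub(";$", "", body)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  labels <- character(0)
  seqs <- list()
  for (r in rows) {
    if (grepl("^'", r)) {
      lab <- sub("^'([^']*)'.*$", "\\1", r)
      rest <- sub("^'[^']*'", "", r)
    } else {
      lab <- sub("^(\\S+).*$", "\\1", r)
      rest <- sub("^\\S+", "", r)
    }
    sq <- toupper(gsub("[[:space:]]", "", rest))
    if (!lab %in% labels) {
      labels <- c(labels, lab)
      seqs[[lab]] <- sq
    } else {
      seqs[[lab]] <- paste0(seqs[[lab]], sq)
    }
  }
  lens <- vapply(seqs, nchar, 1L)
  if (length(unique(lens)) != 1L)
    stop("ragged NEXUS matrix rows: ",
         paste(sprintf("%s=%d", labels, lens[labels]), collapse = ", "))
  aln <- matrix(unlist(strsplit(unlist(seqs[labels]), "")),
                nrow = length(labels), byrow = TRUE,
                dimnames = list(labels, NULL))
  aln[aln == "U"] <- "T"
  validate_alignment(aln)
  # charsets
  cs <- regmatches(txt,
                   gregexpr("(?i)charset\\s+\\S+\\s*=[^;]+;", txt, perl = TRUE))[[1]]
  if (length(cs)) {
    parts <- list()
    for (decl in cs) {
      nm <- sub("(?i)^charset\\s+(\\S+)\\s*=.*$", "\\1", decl, perl = TRUE)
      rng <- sub("(?i)^charset\\s+\\S+\\s*=\\s*([^;]+);$", "\\1", decl,
                 perl = TRUE)
      ix <- integer(0)
      for (tok in strsplit(trimws(rng), "\\s+")[[1]]) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        ix <- c(ix, if (length(ab) == 2L) seq.int(ab[1], ab[2]) else ab)
      }
      parts[[nm]] <- ix
    }
    partitioned_alignment(aln, parts)
  } else {
    partitioned_alignment(aln, list(all = seq_len(ncol(aln))))
  }
}

#' @rdname read_nexus
#' @param pa a [partitioned_alignment].
#' @param interleave write the MATRIX in interleaved blocks of this many
#'   columns; `NULL` (default) writes sequential.
#' @export
write_nexus <- function(pa, path, interleave = NULL) {
  stopifnot(inherits(pa, "partitioned_alignment"))
  aln <- pa$seq
  labs <- rownames(aln)
  qlabs <- ifelse(grepl("[^A-Za-z0-9_.]", labs), paste0("'", labs, "'"), labs)
  pad <- formatC(qlabs, width = max(nchar(qlabs)) + 2L, flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln), ncol(aln)),
             con)
  fmt <- "  FORMAT DATATYPE=DNA MISSING=? GAP=-"
  if (!is.null(interleave)) fmt <- paste0(fmt, " INTERLEAVE")
  writeLines(paste0(fmt, ";"), con)
  writeLines("  MATRIX", con)
  if (is.null(interleave)) {
    for (i in seq_len(nrow(aln)))
      writeLines(paste0("  ", pad[i], paste(aln[i, ], collapse = "")), con)
  } else {
    starts <- seq(1L, ncol(aln), by = interleave)
    for (s in starts) {
      cols <- s:min(s + interleave - 1L, ncol(aln))
      for (i in seq_len(nrow(aln)))
        writeLines(paste0("  ", pad[i],
                          paste(aln[i, cols], collapse = "")), con)
      writeLines("", con)
    }
  }
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (nm in names(pa$parts))
    writeLines(sprintf("  charset %s = %s;", nm, ranges_of(pa$parts[[nm]])),
               con)
  writeLines("END;", con)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()]/[ape::write.tree()] that reject
#' unlabeled leaves, preserve branch lengths to 10 significant digits and
#' round-trip single-quoted labels containing spaces.
#'
#' @param path file path.
#' @return [read_newick()] returns an [ape::phylo] tree;
#'   [write_newick()] returns `path` invisibly.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  # protect quoted labels from ape's tokenizer; a doubled '' inside a
  # quoted label is the Newick escape for a literal quote
  qre <- "'(?:[^']|'')*'"
  quoted <- regmatches(txt, gregexpr(qre, txt, perl = TRUE))[[1]]
  if (length(quoted)) {
    tokens <- sprintf("MCQLAB%dX", seq_along(quoted))
    for (i in seq_along(quoted))
      txt <- sub(qre, tokens[i], txt, perl = TRUE)
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (length(quoted)) {
    orig <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1L),
                 fixed = TRUE)
    ix <- match(tr$tip.label, tokens)
    tr$tip.label[!is.na(ix)] <- orig[ix[!is.na(ix)]]
  }
  if (any(is.na(tr$tip.label) | !nzchar(tr$tip.label)))
    stop("tree in ", path, " has unlabeled leaves")
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label) | !nzchar(tree$tip.label)))
    stop("tree has unlabeled leaves")
  needs_quote <- grepl("[^A-Za-z0-9_.|/-]", tree$tip.label)
  orig <- tree$tip.label
  tokens <- sprintf("MCQLAB%dX", seq_along(orig))
  tree$tip.label[needs_quote] <- tokens[needs_quote]
  txt <- ape::write.tree(tree, digits = 10)
  for (i in which(needs_quote))
    txt <- sub(tokens[i],
               # Newick escapes a quote inside a quoted label by doubling it
               paste0("'", gsub("'", "''", orig[i]), "'"),
               txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}
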