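# Circular genome layouts: gene coordinates, strands, functional categories,
# per-strand origins of replication and replication directions.

#' Construct a genome layout
#'
#' A `genome_layout` describes a circular mitochondrial genome: the 15
#' canonical genes (13 protein-coding + 2 rRNAs) with 1-based inclusive
#' coordinates, the strand each gene sits on (`majority`/`minority`), its
#' functional category (`CO`, `ND`, `AT`, `rRNA`), and, per strand, the
#' origin-of-replication position and the direction replication proceeds in
#' genome coordinates.
#'
#' @param genes data.frame with columns `gene`, `start`, `end`, `strand`,
#'   `category`.
#' @param genome_length circular genome length in bp.
#' @param or_position named numeric, OR coordinate per strand
#'   (`c(majority = , minority = )`).
#' @param replication_direction named character per strand, each
#'   `"increasing"` or `"decreasing"`.
#' @return An object of class `genome_layout`.
#' @export
#' @examples
#' lay <- genome_layout_template("vertebrate")
#' lay
genome_layout <- function(genes, genome_length, or_position,
                          replication_direction) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end", "strand", "category") %in%
                  names(genes)))
  genes$gene <- as.character(genes$gene)
  genes$strand <- as.character(genes$strand)
  genes$category <- as.character(genes$category)
  if (!setequal(genes$gene, MITO_GENES) || nrow(genes) != 15L)
    stop("layout must contain exactly the 15 canonical mitochondrial genes")
  if (anyDuplicated(genes$gene)) stop("duplicated gene names in layout")
  if (!all(genes$strand %in% c("majority", "minority")))
    stop("strand must be 'majority' or 'minority'")
  if (!all(genes$category %in% c("CO", "ND", "AT", "rRNA")))
    stop("category must be one of CO, ND, AT, rRNA")
  if (any(genes$start < 1 | genes$end > genome_length | genes$start > genes$end))
    stop("gene coordinates out of range (wrap-around genes not supported)")
  g <- genes[order(genes$start), ]
  if (any(g$start[-1] <= g$end[-nrow(g)]))
    stop("gene intervals overlap on the circle")
  for (s in c("majority", "minority")) {
    if (is.na(or_position[s]) || or_position[s] < 0 ||
        or_position[s] >= genome_length)
      stop("or_position['", s, "'] must lie in [0, genome_length)")
    if (!replication_direction[s] %in% c("increasing", "decreasing"))
      stop("replication_direction must be 'increasing' or 'decreasing'")
  }
  structure(list(genes = genes, genome_length = as.numeric(genome_length),
                 or_position = or_position[c("majority", "minority")],
                 replication_direction =
                   replication_direction[c("majority", "minority")]),
            class = "genome_layout")
}

#' Bundled genome layout templates
#'
#' Editable gene-map fixtures shipped with the package: a vertebrate layout
#' with human-like gene lengths (all genes on the majority = heavy strand
#' except ND6; heavy-strand OR in the control region, replication proceeding
#' toward CYTB) and a derived-insect layout with Drosophila-like lengths
#' (rRNAs adjacent to the OR on the minority strand; ND1/ND4/ND4L/ND5
#' roughly opposite the OR).
#'
#' @param template `"vertebrate"` or `"insect"`.
#' @return A [genome_layout].
#' @export
genome_layout_template <- function(template = c("vertebrate", "insect")) {
  template <- match.arg(template)
  path <- system.file("extdata", paste0("layout_", template, ".tsv"),
                      package = "mitocong")
  read_gene_map(path)
}

#' Read / write a gene-map TSV
#'
#' The gene-map format is a TSV with columns
#' `gene start end strand category` plus `#key<TAB>value` header lines for
#' `genome_length`, `or_majority`, `or_minority`, `dir_majority`,
#' `dir_minority`. Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return [read_gene_map()] returns a [genome_layout];
#'   [write_gene_map()] returns `path` invisibly.
#' @export
read_gene_map <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "\t")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  need <- c("genome_length", "or_majority", "or_minority",
            "dir_majority", "dir_minority")
  if (!all(need %in% names(meta)))
    stop("gene map ", path, " is missing header fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  genes <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
  genome_layout(
    genes, as.numeric(meta$genome_length),
    or_position = c(majority = as.numeric(meta$or_majority),
                    minority = as.numeric(meta$or_minority)),
    replication_direction = c(majority = meta$dir_majority,
                              minority = meta$dir_minority))
}

#' @rdname read_gene_map
#' @param layout a [genome_layout].
#' @export
write_gene_map <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  hdr <- c(
    paste0("#genome_length\t", format(layout$genome_length, scientific = FALSE)),
    paste0("#or_majority\t", layout$or_position[["majority"]]),
    paste0("#or_minority\t", layout$or_position[["minority"]]),
    paste0("#dir_majority\t", layout$replication_direction[["majority"]]),
    paste0("#dir_minority\t", layout$replication_direction[["minority"]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(layout$genes[, c("gene", "start", "end", "strand", "category")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", nrow(x$genes), "genes on a circular genome of",
      format(x$genome_length, scientific = FALSE), "bp\n")
  cat("  OR (majority):", x$or_position[["majority"]], "replicating",
      x$replication_direction[["majority"]], "\n")
  cat("  OR (minority):", x$or_position[["minority"]], "replicating",
      x$replication_direction[["minority"]], "\n")
  cat("  minority-strand genes:",
      paste(x$genes$gene[x$genes$strand == "minority"], collapse = ", "), "\n")
  invisible(x)
}

#' Gene lengths of a layout
#' @param layout a [genome_layout].
#' @return Named integer vector of gene lengths in bp.
#' @export
gene_lengths <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  setNames(as.integer(layout$genes$end - layout$genes$start + 1),
           layout$genes$gene)
}
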