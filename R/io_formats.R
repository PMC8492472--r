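## Readers/writers for the standard formats the pipeline touches.
## Internal coordinates are 0-based half-open throughout; conversion to and
## from 1-based happens only at the VCF/MAF boundary.

#' Species tags recognised in heptad gene trees
#'
#' Leaf labels follow the convention `"<species_tag>|<gene_id>"`.
#' @export
allokit_species_tags <- c("zebrafish", "pguichenoti", "ptetrazona",
                          "carp", "goldfish")

#' Parse a newick gene tree
#'
#' Thin wrapper around [ape::read.tree()] with an upfront structural check
#' that reports the character offset of the first unbalanced parenthesis,
#' which `ape` does not.
#'
#' @param text a newick string (may include branch lengths and integer
#'   node supports as internal node labels).
#' @return an object of class `phylo`.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stopf("malformed newick: unbalanced ')' at offset %d", i)
    }
  }
  if (depth != 0L)
    stopf("malformed newick: %d unclosed '(' at end of string", depth)
  if (!grepl(";\\s*$", text))
    stopf("malformed newick: missing terminal ';' at offset %d", nchar(text))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stopf("malformed newick: parse failed")
  if (anyDuplicated(tr$tip.label))
    stopf("leaf labels are not unique")
  tr
}

#' Serialise a tree back to newick
#'
#' @param tree a `phylo` object.
#' @return a newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Split heptad leaf labels into species tag and gene id
#'
#' @param labels character vector of `"species|gene"` labels.
#' @return a data.frame with columns `label`, `species`, `gene_id`.
#' @export
split_leaf_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stopf("leaf label '%s' is not of the form species|gene", labels[bad][1])
  out <- data.frame(label = labels,
                    species = vapply(parts, `[[`, "", 1L),
                    gene_id = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$species), allokit_species_tags)
  if (length(unknown))
    stopf("unknown species tag '%s'", unknown[1])
  out
}

#' Read alignment blocks from a MAF file
#'
#' Parses the "a"/"s" record dialect of the multiple-alignment format.
#' Negative-strand rows are converted to forward-strand 0-based half-open
#' intervals (`start' = srcSize - start - size`), which requires the source
#' size field.
#'
#' @param path path to a MAF file, or a character vector of MAF lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a list of alignment blocks; each block is a list with
#'   `block_id`, `rows` (data.frame: `genome_id`, `chromosome`, `start`,
#'   `end`, `strand`) and `length` (the widest row span in bp).
#' @export
read_maf_blocks <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur) || nrow(cur$rows) == 0L) return(blocks)
    cur$length <- max(cur$rows$end - cur$rows$start)
    c(blocks, list(cur))
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list(block_id = sprintf("block_%d", length(blocks) + 1L),
                  rows = data.frame(genome_id = character(),
                                    chromosome = character(),
                                    start = numeric(), end = numeric(),
                                    strand = character(),
                                    stringsAsFactors = FALSE))
      m <- regmatches(ln, regexec("id=(\\S+)", ln))[[1]]
      if (length(m) == 2L) cur$block_id <- m[2]
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      if (is.null(cur)) stopf("MAF 's' line before any 'a' line")
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 6L) stopf("MAF 's' line with fewer than 6 fields")
      src <- f[2]
      start <- as.numeric(f[3])
      size <- as.numeric(f[4])
      strand <- f[5]
      src_size <- suppressWarnings(as.numeric(f[6]))
      if (!strand %in% c("+", "-"))
        stopf("MAF strand field must be '+' or '-', got '%s'", strand)
      if (strand == "-") {
        if (is.na(src_size))
          stopf("negative-strand MAF row without source size: cannot convert")
        start <- src_size - start - size
      }
      dot <- regexpr(".", src, fixed = TRUE)
      if (dot > 0) {
        genome <- substr(src, 1L, dot - 1L)
        chrom <- substr(src, dot + 1L, nchar(src))
      } else {
        genome <- src
        chrom <- src
      }
      cur$rows <- rbind(cur$rows, data.frame(
        genome_id = genome, chromosome = chrom,
        start = start, end = start + size, strand = strand,
        stringsAsFactors = FALSE))
    }
  }
  blocks <- flush(cur, blocks)
  bad <- vapply(blocks, function(b) any(b$rows$end <= b$rows$start), TRUE)
  if (any(bad)) stopf("MAF block with non-positive row span")
  blocks
}

#' Write alignment blocks to a MAF file
#'
#' Inverse of [read_maf_blocks()]: internal forward-strand 0-based
#' half-open intervals are emitted, negative-strand rows re-expressed in
#' the MAF's reverse-strand coordinates.  `src_sizes` supplies the source
#' sequence length per `"genome.chromosome"` key (required for any
#' negative-strand row).
#'
#' @param blocks list of blocks as returned by [read_maf_blocks()].
#' @param path output file path.
#' @param src_sizes named numeric vector of source sizes.
#' @return `path`, invisibly.
#' @export
write_maf_blocks <- function(blocks, path, src_sizes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(sprintf("a id=%s", b$block_id), con)
    for (i in seq_len(nrow(b$rows))) {
      r <- b$rows[i, ]
      key <- paste0(r$genome_id, ".", r$chromosome)
      size <- r$end - r$start
      src_size <- src_sizes[[key]]
      if (is.null(src_size) || is.na(src_size))
        stopf("no source size for '%s'", key)
      start <- if (r$strand == "-") src_size - r$start - size else r$start
      writeLines(sprintf("s %s %d %d %s %d *", key, as.integer(start),
                         as.integer(size), r$strand, as.integer(src_size)),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a minimal genotype matrix from a VCF file
#'
#' Keeps biallelic SNPs only (multiallelic and non-SNP records are dropped
#' and counted), mirroring a SNP-only SelectVariants split.  Genotypes are
#' returned as alternate-allele dosages 0/1/2 with missing calls as `NA`.
#'
#' @param path path to a VCF 4.x file with a GT FORMAT field.
#' @return a `genotype_matrix`: list with `sample_ids`, `sites`
#'   (data.frame `chromosome`, `position` (1-based bp), `ref`, `alt`),
#'   `genotypes` (site x sample dosage matrix) and `n_dropped`.
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(genotype_matrix(character(), data.frame(), matrix(0, 0, 0),
                           n_dropped = 0L))
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stopf("VCF has records without a GT format field")
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean == "0/0"] <- 0
  dosage[clean %in% c("0/1", "1/0")] <- 1
  dosage[clean == "1/1"] <- 2
  sites <- data.frame(chromosome = fix$CHROM,
                      position = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), sites, dosage, n_dropped = n_dropped)
}

#' Construct a genotype matrix container
#'
#' @param sample_ids character vector of sample names.
#' @param sites data.frame with `chromosome`, `position`, `ref`, `alt`;
#'   positions must be strictly increasing within a chromosome.
#' @param genotypes site x sample matrix of alt-allele dosages (0/1/2/NA).
#' @param population_of optional named character vector sample -> population.
#' @param n_dropped count of records dropped on import.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, sites, genotypes,
                            population_of = NULL, n_dropped = 0L) {
  if (nrow(sites) > 0L) {
    ord_ok <- tapply(sites$position, sites$chromosome,
                     function(p) all(diff(p) > 0))
    if (!all(unlist(ord_ok)))
      stopf("positions must be strictly increasing within a chromosome")
  }
  structure(list(sample_ids = sample_ids, sites = sites,
                 genotypes = genotypes, population_of = population_of,
                 n_dropped = n_dropped),
            class = "genotype_matrix")
}

#' Summarise chromosome anchoring of an assembly
#'
#' @param chromosome_lengths numeric vector of anchored chromosome sizes (Mb).
#' @param assembly_size total assembly size (Mb); must be at least the
#'   anchored total.
#' @return list with `anchored_fraction` (percent, 1 decimal, half-up),
#'   `mean_chromosome_size` (Mb, 2 decimals) and `n_chromosomes`.
#' @export
summarize_anchoring <- function(chromosome_lengths, assembly_size) {
  n <- length(chromosome_lengths)
  if (n == 0L) stopf("no chromosomes supplied")
  total <- sum(chromosome_lengths)
  if (total <= 0) stopf("anchored total must be positive")
  if (assembly_size < total)
    stopf("assembly size (%g) smaller than anchored total (%g)",
          assembly_size, total)
  list(anchored_fraction = round_half_up(100 * total / assembly_size, 1),
       mean_chromosome_size = round_half_up(total / n, 2),
       n_chromosomes = n)
}
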