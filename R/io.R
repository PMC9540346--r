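# Readers and writers for the plain-text formats the pipeline consumes and
# emits: BED (0-based half-open), minimal GTF, chrom sizes, triplet count
# matrices, JASPAR-style PFM text, and a minimal MEME motif writer.
# FASTA goes through Biostrings.

#' Read a BED file of peaks or CNEs
#'
#' Coordinates stay in the BED convention: 0-based, half-open. Columns beyond
#' the sixth are ignored; missing name/score/strand columns are filled.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(
    chrom  = as.character(df[[1L]]),
    start  = as.integer(df[[2L]]),
    end    = as.integer(df[[3L]]),
    name   = if (ncol(df) >= 4L) as.character(df[[4L]]) else
      paste0("feature_", seq_len(nrow(df))),
    score  = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else 0,
    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else ".",
    stringsAsFactors = FALSE
  )
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1L], ": ", path)
  out
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom  = df$chrom,
    start  = as.integer(df$start),
    end    = as.integer(df$end),
    name   = df$name %||% df$peak_id %||% paste0("feature_", seq_len(nrow(df))),
    score  = df$score %||% 0,
    strand = df$strand %||% ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome sizes table (chrom <TAB> length)
#' @param path two-column TSV.
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(chrom = names(sizes), length = as.integer(sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a minimal GTF
#'
#' Only lines whose feature type is \code{gene} are used; \code{gene_id} is
#' extracted from the attribute column by key. GTF is 1-based closed; the
#' returned coordinates are converted to 0-based half-open to match the rest
#' of the pipeline.
#'
#' @param path GTF path.
#' @return data.frame with gene_id, chrom, strand, start, end, tss
#'   (0-based half-open; tss = start for '+', end - 1 for '-').
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), tss = integer(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9L && x[3L] == "gene", logical(1))
  f <- f[keep]
  gene_id <- vapply(f, function(x) {
    m <- regmatches(x[9L], regexec("gene_id[ =]+\"?([^\";]+)\"?", x[9L]))[[1L]]
    if (length(m) < 2L) stop("GTF gene line without gene_id attribute")
    m[2L]
  }, character(1))
  start1 <- vapply(f, function(x) as.integer(x[4L]), integer(1))
  end1   <- vapply(f, function(x) as.integer(x[5L]), integer(1))
  strand <- vapply(f, function(x) x[7L], character(1))
  df <- data.frame(
    gene_id = gene_id,
    chrom   = vapply(f, function(x) x[1L], character(1)),
    strand  = strand,
    start   = start1 - 1L,          # to 0-based half-open
    end     = end1,
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' @rdname read_gtf_genes
#' @param genes data.frame as returned by [read_gtf_genes()] or
#'   [make_genome()] (0-based half-open).
#' @param source source field for the emitted lines.
#' @export
write_gtf_genes <- function(genes, path, source = "regenhancer") {
  if (nrow(genes)) {
    lines <- sprintf(
      "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"protein_coding\";",
      genes$chrom, source, genes$start + 1L, genes$end, genes$strand,
      genes$gene_id)
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read/write triplet count matrices
#'
#' Sparse triplet TSV with header \code{cell_id  peak_id  count}; zeros are
#' omitted on disk. The dense form is peaks x cells.
#'
#' @param path triplet TSV path.
#' @param peak_ids,cell_ids row/column universe. Required so all-zero peaks
#'   or cells are not silently dropped.
#' @return integer matrix, peaks in rows, cells in columns.
#' @export
read_counts_triplet <- function(path, peak_ids, cell_ids) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- matrix(0L, nrow = length(peak_ids), ncol = length(cell_ids),
              dimnames = list(peak_ids, cell_ids))
  if (nrow(df)) {
    i <- match(df$peak_id, peak_ids)
    j <- match(df$cell_id, cell_ids)
    if (anyNA(i) || anyNA(j))
      stop("triplet file references unknown peak or cell ids: ", path)
    m[cbind(i, j)] <- as.integer(df$count)
  }
  m
}

#' @rdname read_counts_triplet
#' @param counts peaks x cells integer matrix with dimnames.
#' @export
write_counts_triplet <- function(counts, path) {
  nz <- which(counts != 0L, arr.ind = TRUE)
  df <- data.frame(
    cell_id = colnames(counts)[nz[, 2L]],
    peak_id = rownames(counts)[nz[, 1L]],
    count   = counts[nz],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cell_id, df$peak_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-style PFM text file
#'
#' Records look like \code{">ID NAME"} followed by four whitespace-separated
#' count rows in A, C, G, T order (bare or in the
#' \code{A [ 1 2 3 ]} bracket style). Counts are converted to
#' column-stochastic probability matrices.
#'
#' @param path PFM text file.
#' @return named list of 4 x width probability matrices with rownames
#'   A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no PFM records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(header, "\\s+")[[1L]][1L]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) < 4L) stop("PFM record ", id, " has fewer than 4 rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("ragged PFM record: ", id)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    cs <- colSums(m)
    if (any(cs <= 0)) stop("PFM record ", id, " has a zero column")
    out[[id]] <- sweep(m, 2L, cs, "/")
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pfms named list of 4 x width matrices (probabilities or counts).
#' @param counts_scale rows are written as pseudo-counts scaled to this total
#'   per column.
#' @export
write_jaspar_pfm <- function(pfms, path, counts_scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    m <- pfms[[id]]
    m <- sweep(m, 2L, colSums(m), "/") * counts_scale
    writeLines(paste0(">", id, " ", id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(formatC(m[b, ], format = "f", digits = 2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write de novo motifs in minimal MEME format
#'
#' @param motifs list of motifs as returned by [extract_denovo_motifs()]
#'   (each has `pwm`, `filter_index`, `n_sites`).
#' @param path output path.
#' @param background background base frequencies (A, C, G, T).
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1L],
                       background[2L], background[3L], background[4L]), ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF filter_%d", m$filter_index), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m$pwm), m$n_sites), con)
    for (j in seq_len(ncol(m$pwm)))
      writeLines(paste(formatC(m$pwm[, j], format = "f", digits = 6),
                       collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write 400 bp element FASTA
#'
#' Thin wrappers over Biostrings with the 60-column wrap the generator
#' guarantees.
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
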