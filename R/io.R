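# Sequence and annotation input, and the four prediction output files.

#' Construct a genome sequence record
#'
#' A genome record holds one contig: an identifier, its nucleotide sequence
#' over the alphabet `{A,C,G,T,N}` (uppercased on construction) and a flag
#' marking the molecule as circular.
#'
#' @param id Contig identifier.
#' @param seq Nucleotide string; lowercase is accepted and uppercased.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `zgene_genome` with elements `id`, `seq`,
#'   `length` and `circular`.
#' @examples
#' g <- genome_sequence("chr", "atgaaatag")
#' g$length
#' @export
genome_sequence <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'", call. = FALSE)
  # validates the alphabet, naming the record in any error
  invisible(seq_to_int(seq, what = sprintf("record '%s'", id)))
  structure(list(id = id, seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "zgene_genome")
}

#' @export
print.zgene_genome <- function(x, ...) {
  cat(sprintf("<zgene_genome> %s: %d nt%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

as_genome_list <- function(x) {
  if (inherits(x, "zgene_genome")) return(stats::setNames(list(x), x$id))
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "zgene_genome")))
  ids <- vapply(x, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate contig ids in genome set", call. = FALSE)
  stats::setNames(x, ids)
}

#' Read a (multi-)FASTA genome file
#'
#' Reads one or more contigs from a FASTA file. Multi-record files are the
#' normal case for draft-genome contigs. Lowercase bases are uppercased;
#' any character outside `{A,C,G,T,N}` is an error naming the offending
#' record and character.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled over records; marks contigs circular.
#' @return A named list of [genome_sequence()] records, in file order.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  circular <- rep_len(circular, length(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    out[[i]] <- genome_sequence(ids[i], as.character(ss[[i]]), circular[i])
  }
  as_genome_list(out)
}

#' Read a gene annotation table (PTT or TSV)
#'
#' Supports the RefSeq protein-table (PTT) dialect, whose `Location` column
#' holds `start..end` with a separate strand column, and a minimal TSV
#' dialect with `start`, `end`, `strand` columns (a header row and an
#' optional `contig` column are recognised; `#` comment lines are skipped).
#' Coordinates are 1-based inclusive. A length divisible by 3 is not
#' required (annotation quirks are tolerated with a warning).
#'
#' @param path Path to the annotation file.
#' @param dialect `"ptt"` or `"tsv"`.
#' @param contig Contig id to assign when the file carries none.
#' @param contig_lengths Optional named vector of contig lengths used to
#'   check that coordinates fall inside their contig.
#' @return A data.frame with columns `contig`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "ptt"), contig = NA_character_,
                            contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ann <- if (dialect == "ptt") parse_ptt(lines, contig) else parse_ann_tsv(lines, contig)
  bad <- which(ann$end < ann$start & !ann$wrap)
  if (length(bad)) {
    stop(sprintf("annotation line %d: end (%d) < start (%d)",
                 ann$line[bad[1L]], ann$end[bad[1L]], ann$start[bad[1L]]),
         call. = FALSE)
  }
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[ann$contig]
    out_of_range <- which(!is.na(len) & (ann$start < 1L | ann$end > len) & !ann$wrap)
    if (length(out_of_range)) {
      stop(sprintf("annotation line %d: coordinates outside contig length",
                   ann$line[out_of_range[1L]]), call. = FALSE)
    }
  }
  if (any((ann$end - ann$start + 1L) %% 3L != 0L & !ann$wrap)) {
    warning("some annotated gene lengths are not divisible by 3", call. = FALSE)
  }
  ann[c("contig", "start", "end", "strand")]
}

parse_ptt <- function(lines, contig) {
  body <- grep("^[0-9]+\\.\\.[0-9]+\t", lines)
  if (!length(body)) stop("no PTT data lines found", call. = FALSE)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  loc <- vapply(fields, `[[`, "", 1L)
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))
  bad <- which(vapply(m, length, 0L) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed PTT Location field at line %d: '%s'",
                 body[bad[1L]], loc[bad[1L]]), call. = FALSE)
  }
  strand <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
  if (!all(strand %in% c("+", "-"))) {
    i <- which(!(strand %in% c("+", "-")))[1L]
    stop(sprintf("bad strand '%s' at line %d", strand[i], body[i]), call. = FALSE)
  }
  data.frame(contig = contig,
             start = as.integer(vapply(m, `[[`, "", 2L)),
             end = as.integer(vapply(m, `[[`, "", 3L)),
             strand = strand, wrap = FALSE, line = body,
             stringsAsFactors = FALSE)
}

parse_ann_tsv <- function(lines, contig) {
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop("no annotation lines found", call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  named <- all(c("start", "end", "strand") %in% tolower(header))
  if (named) {
    cols <- tolower(header)
    fields <- fields[-1L]
    keep <- keep[-1L]
    pick <- function(f, name, default = NA_character_) {
      i <- match(name, cols)
      if (is.na(i) || i > length(f)) default else f[[i]]
    }
    start <- vapply(fields, pick, "", "start")
    end <- vapply(fields, pick, "", "end")
    strand <- vapply(fields, pick, "", "strand")
    ctg <- vapply(fields, pick, "", "contig")
    wrap <- vapply(fields, pick, "", "wrap", default = "FALSE")
    if (all(is.na(ctg))) ctg <- rep(contig, length(fields))
  } else {
    if (any(vapply(fields, length, 0L) < 3L)) {
      i <- which(vapply(fields, length, 0L) < 3L)[1L]
      stop(sprintf("annotation line %d: expected at least 3 tab-separated fields",
                   keep[i]), call. = FALSE)
    }
    start <- vapply(fields, `[[`, "", 1L)
    end <- vapply(fields, `[[`, "", 2L)
    strand <- vapply(fields, `[[`, "", 3L)
    ctg <- rep(contig, length(fields))
    wrap <- rep("FALSE", length(fields))
  }
  s <- suppressWarnings(as.integer(start))
  e <- suppressWarnings(as.integer(end))
  if (anyNA(s) || anyNA(e)) {
    i <- which(is.na(s) | is.na(e))[1L]
    stop(sprintf("annotation line %d: non-numeric coordinates", keep[i]),
         call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    i <- which(!(strand %in% c("+", "-")))[1L]
    stop(sprintf("annotation line %d: bad strand '%s'", keep[i], strand[i]),
         call. = FALSE)
  }
  data.frame(contig = ctg, start = s, end = e, strand = strand,
             wrap = toupper(wrap) == "TRUE", line = keep,
             stringsAsFactors = FALSE)
}

#' Genomic slice of a gene in reading orientation
#'
#' Extracts `[start, end]` from a contig and reverse-complements it for
#' reverse-strand genes, so the result always reads 5'->3' from start codon
#' to stop codon. Origin-wrapping genes on circular contigs (`start > end`,
#' `wrap = TRUE`) are stitched across the origin.
#'
#' @param genome A [genome_sequence()] record.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @param wrap Does the gene cross the origin of a circular contig?
#' @return The gene DNA as a character string.
#' @export
gene_dna <- function(genome, start, end, strand, wrap = FALSE) {
  s <- if (wrap) paste0(substr(genome$seq, start, genome$length),
                        substr(genome$seq, 1L, end))
       else substr(genome$seq, start, end)
  if (strand == "-") reverse_complement(s) else s
}

#' Translate coding sequences (genetic code 11)
#'
#' Translates gene DNA (including the stop codon, which is removed before
#' translation) using the bacterial/archaeal genetic code. Codons containing
#' `N` translate to `X`; initiator GTG/TTG are rendered as `M`.
#'
#' @param seqs Character vector of gene DNA sequences (5'->3', lengths
#'   divisible by 3, stop codon included).
#' @return Character vector of protein sequences of length `nchar/3 - 1`.
#' @export
translate_genes <- function(seqs) {
  stopifnot(all(nchar(seqs) %% 3L == 0L), all(nchar(seqs) >= 6L))
  body <- substr(seqs, 1L, nchar(seqs) - 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(body),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = FALSE))
  # bacterial convention: alternative initiators read as Met
  first <- toupper(substr(body, 1L, 3L))
  init <- first %in% c("ATG", "GTG", "TTG")
  substr(aa[init], 1L, 1L) <- "M"
  unname(aa)
}

output_header <- function(params) {
  c(sprintf("# zgene %s", zgene_version()),
    sprintf("# %s", params))
}

#' Write prediction output files
#'
#' Writes up to four artifacts for a set of gene predictions: a TSV of
#' chromosomal coordinates, a FASTA of gene DNA sequences (`.ffn`), a FASTA
#' of conceptual translations (`.faa`) and a TSV of per-gene essentiality
#' scores and calls.
#'
#' @param predictions Prediction data.frame (as in a [zgene()] fit's
#'   `$predictions`): columns `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `length`, `coding_score`, optionally `wrap`, `essentiality_score`,
#'   `essential_call`.
#' @param genomes A genome record or list of records covering all contigs.
#' @param out_prefix Path prefix for the output files.
#' @param what Which artifacts to write: subset of `"coords"`,
#'   `"nucleotide"`, `"protein"`, `"essentiality"`.
#' @param params Character scalar recorded in each file's comment header.
#' @return Invisibly, the named vector of files written.
#' @export
write_gene_outputs <- function(predictions, genomes, out_prefix,
                               what = c("coords", "nucleotide", "protein"),
                               params = "") {
  what <- match.arg(what, c("coords", "nucleotide", "protein", "essentiality"),
                    several.ok = TRUE)
  genomes <- as_genome_list(genomes)
  p <- predictions
  if (is.null(p$wrap)) p$wrap <- FALSE
  files <- character(0)
  hdr <- output_header(params)

  if ("coords" %in% what) {
    f <- paste0(out_prefix, "_genes.tsv")
    tab <- data.frame(gene_id = p$gene_id, contig = p$contig,
                      start = p$start, end = p$end, strand = p$strand,
                      length = p$length, coding_score = p$coding_score,
                      wrap = p$wrap, stringsAsFactors = FALSE)
    writeLines(hdr, f)
    suppressWarnings(utils::write.table(tab, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    files["coords"] <- f
  }
  if (any(c("nucleotide", "protein") %in% what)) {
    dna <- vapply(seq_len(nrow(p)), function(i)
      gene_dna(genomes[[p$contig[i]]], p$start[i], p$end[i], p$strand[i],
               p$wrap[i]), "")
    if ("nucleotide" %in% what) {
      f <- paste0(out_prefix, "_genes.ffn")
      ss <- Biostrings::DNAStringSet(dna)
      names(ss) <- sprintf("%s %s:%d-%d(%s)", p$gene_id, p$contig, p$start,
                           p$end, p$strand)
      Biostrings::writeXStringSet(ss, f)
      files["nucleotide"] <- f
    }
    if ("protein" %in% what) {
      f <- paste0(out_prefix, "_proteins.faa")
      aa <- Biostrings::AAStringSet(translate_genes(dna))
      names(aa) <- sprintf("%s %s:%d-%d(%s)", p$gene_id, p$contig, p$start,
                           p$end, p$strand)
      Biostrings::writeXStringSet(aa, f)
      files["protein"] <- f
    }
  }
  if ("essentiality" %in% what) {
    if (is.null(p$essentiality_score) || anyNA(p$essentiality_score)) {
      stop("essentiality output requested but scores are missing", call. = FALSE)
    }
    f <- paste0(out_prefix, "_essentiality.tsv")
    tab <- data.frame(gene_id = p$gene_id,
                      essentiality_score = p$essentiality_score,
                      call = p$essential_call, stringsAsFactors = FALSE)
    writeLines(hdr, f)
    suppressWarnings(utils::write.table(tab, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    files["essentiality"] <- f
  }
  invisible(files)
}
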