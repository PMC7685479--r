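#' Variant classification vocabularies
#'
#' The MAF `Variant_Classification` controlled vocabulary, the default set of
#' classes retained as potentially pathogenic (the standard non-synonymous
#' convention), and the truncating subset used by the 20/20 classifier.
#'
#' @return Character vector of classification labels.
#' @export
maf_pathogenic_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' @rdname maf_pathogenic_classes
#' @export
maf_truncating_classes <- function() {
  c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
    "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site")
}

#' @rdname maf_pathogenic_classes
#' @export
maf_vocabulary <- function() {
  c(maf_pathogenic_classes(),
    "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
    "RNA", "IGR", "Targeted_Region")
}

#' Construct a table of somatic variant records
#'
#' Variant records are plain data frames with one row per mutation call:
#' `gene`, `sample`, `classification`, and optional `protein_position`,
#' `chromosome`, `start` (1-based), `sift`, `polyphen`.
#'
#' @param gene,sample,classification Character vectors (recycled to a common
#'   length); gene symbols are case-normalized.
#' @param protein_position Optional integer vector (NA allowed), 1-based amino
#'   acid position.
#' @param chromosome,start,sift,polyphen Optional annotation columns.
#' @return A `data.frame` of variant records.
#' @export
variant_records <- function(gene, sample, classification,
                            protein_position = NA_integer_,
                            chromosome = NA_character_, start = NA_integer_,
                            sift = NA_character_, polyphen = NA_character_) {
  df <- data.frame(gene = normalize_symbols(gene),
                   sample = as.character(sample),
                   classification = as.character(classification),
                   protein_position = as.integer(protein_position),
                   chromosome = as.character(chromosome),
                   start = as.integer(start),
                   sift = as.character(sift),
                   polyphen = as.character(polyphen),
                   stringsAsFactors = FALSE)
  stopifnot(all(nzchar(df$gene)), all(nzchar(df$sample)))
  bad <- df$protein_position[!is.na(df$protein_position)] < 1L
  if (any(bad)) stop("protein_position must be >= 1 when present")
  df
}

empty_variant_records <- function() {
  variant_records(character(0), character(0), character(0),
                  integer(0), character(0), integer(0),
                  character(0), character(0))
}

# First integer embedded in a protein-change string ("p.R175H" -> 175).
parse_protein_position <- function(x) {
  x <- as.character(x)
  has <- grepl("[0-9]", x)
  out <- rep(NA_integer_, length(x))
  out[has] <- as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", x[has]))
  out
}

#' Read a Mutation Annotation Format (MAF) file
#'
#' Reads the tab-separated MAF dialect: a header row with at least
#' `Hugo_Symbol`, `Tumor_Sample_Barcode` and `Variant_Classification`,
#' comment lines starting with `#` skipped. `Protein_Change` or
#' `HGVSp_Short` is parsed for the protein position (the first integer in
#' e.g. "p.R175H"); `Chromosome`/`Start_Position` and `SIFT`/`PolyPhen`
#' columns are carried along when present. Gzip-compressed files are
#' accepted.
#'
#' @param path Path to a MAF file (.maf, .tsv, optionally .gz).
#' @return A variant-record data frame (see [variant_records()]).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L || !nzchar(first[1L])) {
    warning("MAF file is empty: ", path)
    return(empty_variant_records())
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  mandatory <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("MAF is missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("MAF file has a header but no records: ", path)
    return(empty_variant_records())
  }
  pcol <- intersect(c("Protein_Change", "HGVSp_Short"), names(df))
  ppos <- if (length(pcol)) parse_protein_position(df[[pcol[1L]]]) else NA_integer_
  getcol <- function(nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  start <- suppressWarnings(as.integer(getcol("Start_Position")))
  variant_records(df$Hugo_Symbol, df$Tumor_Sample_Barcode,
                  df$Variant_Classification,
                  protein_position = ppos,
                  chromosome = getcol("Chromosome"), start = start,
                  sift = getcol("SIFT"), polyphen = getcol("PolyPhen"))
}

#' Write variant records as a MAF file
#'
#' Emits the tab-separated columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, `Protein_Change` plus optional coordinate and
#' impact columns, so that [read_maf()] round-trips all mandatory fields.
#'
#' @param records Variant-record data frame.
#' @param path Output path.
#' @export
write_maf <- function(records, path) {
  pc <- ifelse(is.na(records$protein_position), "",
               paste0("p.X", records$protein_position, "X"))
  out <- data.frame(Hugo_Symbol = records$gene,
                    Tumor_Sample_Barcode = records$sample,
                    Variant_Classification = records$classification,
                    Protein_Change = pc,
                    Chromosome = ifelse(is.na(records$chromosome), "",
                                        records$chromosome),
                    Start_Position = ifelse(is.na(records$start), "",
                                            records$start),
                    SIFT = ifelse(is.na(records$sift), "", records$sift),
                    PolyPhen = ifelse(is.na(records$polyphen), "",
                                      records$polyphen),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain potentially pathogenic variant records
#'
#' Keeps exactly the records whose `Variant_Classification` is in
#' `retained_classes`, preserving order. Classifications outside the MAF
#' vocabulary are dropped and counted in a message.
#'
#' @param records Variant-record data frame.
#' @param retained_classes Character vector of classifications to keep;
#'   defaults to the standard non-synonymous set.
#' @return The filtered records.
#' @export
filter_pathogenic <- function(records, retained_classes = maf_pathogenic_classes()) {
  stopifnot(length(retained_classes) > 0L)
  unknown <- !(records$classification %in% maf_vocabulary())
  if (any(unknown))
    ds_message(sum(unknown), " record(s) with unknown Variant_Classification dropped")
  keep <- records$classification %in% retained_classes
  records[keep, , drop = FALSE]
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated, first column gene symbols, remaining columns samples.
#' Duplicate gene rows are collapsed by `collapse` ("mean" by default);
#' empty or "NA" cells become missing values; any other non-numeric cell is
#' an error reporting its coordinates; ragged rows are an error reporting
#' the row number.
#'
#' @param path Path to TSV (optionally gzipped).
#' @param collapse How to combine duplicated gene rows: "mean" or "first".
#' @return Numeric matrix, genes in rows (case-normalized), samples in columns.
#' @export
read_expression <- function(path, collapse = c("mean", "first")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop("ragged expression table: row ", which(nf != nf[1L])[1L],
         " has ", nf[which(nf != nf[1L])[1L]], " fields, expected ", nf[1L])
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column")
  if (anyDuplicated(names(df)[-1L])) stop("duplicate sample columns")
  genes <- normalize_symbols(df[[1L]])
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(NULL, names(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- trimws(df[[j + 1L]])
    miss <- !nzchar(v) | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- !miss & is.na(num)
    if (any(bad))
      stop("non-numeric cell at row ", which(bad)[1L], " (gene ",
           genes[which(bad)[1L]], "), column '", names(df)[j + 1L], "': '",
           v[which(bad)[1L]], "'")
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    if (collapse == "first") {
      keep <- !duplicated(genes)
      vals <- vals[keep, , drop = FALSE]
      genes <- genes[keep]
    } else {
      sums <- rowsum(ifelse(is.na(vals), 0, vals), genes)
      cnts <- rowsum((!is.na(vals)) + 0, genes)
      vals <- sums / ifelse(cnts == 0, NA, cnts)
      genes <- rownames(vals)
    }
  }
  rownames(vals) <- genes
  vals
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param gene_column Header for the first (gene) column.
#' @export
write_expression <- function(mat, path, gene_column = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Member symbols are case-normalized and de-duplicated within a set.
#'
#' @param path Path to a GMT file (optionally gzipped).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  sets <- lapply(parts, function(p) unique(normalize_symbols(p[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- nms
  sets
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain text file (optionally gzipped).
#' @return Character vector of unique, case-normalized symbols.
#' @export
read_gene_list <- function(path) {
  x <- normalize_symbols(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a gene annotation catalog
#'
#' CSV or TSV (auto-detected from the header line) with a `gene` column,
#' a `known_cancer_gene` flag (COSMIC-style membership) and optional
#' `gene_length` (bp) / `protein_length` (aa) columns.
#'
#' @param path Path to the catalog.
#' @return A data frame with columns `gene`, `known_cancer_gene`,
#'   `gene_length`, `protein_length` (lengths NA when absent from the file).
#' @export
read_gene_catalog <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("catalog needs a 'gene' column")
  gene <- normalize_symbols(df$gene)
  if (anyDuplicated(gene))
    stop("duplicate catalog symbol: ", gene[duplicated(gene)][1L])
  known <- if ("known_cancer_gene" %in% names(df)) {
    v <- df$known_cancer_gene
    if (is.character(v)) v %in% c("1", "TRUE", "true", "yes") else as.logical(v)
  } else rep(FALSE, length(gene))
  getlen <- function(nm) {
    if (nm %in% names(df)) as.numeric(df[[nm]]) else rep(NA_real_, length(gene))
  }
  out <- data.frame(gene = gene, known_cancer_gene = known,
                    gene_length = getlen("gene_length"),
                    protein_length = getlen("protein_length"),
                    stringsAsFactors = FALSE)
  if (any(out$gene_length <= 0, na.rm = TRUE) ||
      any(out$protein_length <= 0, na.rm = TRUE))
    stop("catalog lengths must be positive when present")
  out
}
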