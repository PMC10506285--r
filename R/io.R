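#' Read a 10x-style triplet layout into a spot_dataset
#'
#' Expects the standard trio — a MatrixMarket counts matrix (1-based indices,
#' genes x barcodes), a gene list and a barcode list (one id per line; a
#' tab-separated features file is accepted, the first column is used) — plus a
#' Visium-style positions table with columns
#' `barcode,in_tissue,array_row,array_col,pxl_row,pxl_col`. Spots missing from
#' the positions table are an error: geometry is required downstream.
#'
#' @param matrix_path MatrixMarket .mtx file.
#' @param genes_path one gene id per line (first tab field used).
#' @param barcodes_path one barcode per line.
#' @param positions_path positions CSV (with or without header).
#' @param annotations optional data.frame with columns
#'   `spot_id,sample_id,group` and optionally `cluster`/`compartment`; when
#'   absent all spots are assigned sample "S1", group "g1".
#' @return a validated [spot_dataset()].
#' @export
read_10x_triplet <- function(matrix_path, genes_path, barcodes_path,
                             positions_path, annotations = NULL) {
  for (p in c(matrix_path, genes_path, barcodes_path, positions_path))
    if (!file.exists(p)) sl_format_error("input file not found: %s", p)

  counts <- tryCatch(Matrix::readMM(matrix_path),
                     error = function(e) sl_format_error(
                       "malformed MatrixMarket file %s: %s", matrix_path, conditionMessage(e)))
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(counts) != length(genes))
    sl_format_error("%s: matrix has %d rows but %s lists %d genes",
                    matrix_path, nrow(counts), genes_path, length(genes))
  if (ncol(counts) != length(barcodes))
    sl_format_error("%s: matrix has %d columns but %s lists %d barcodes",
                    matrix_path, ncol(counts), barcodes_path, length(barcodes))
  if (anyDuplicated(barcodes))
    sl_validation_error("duplicate barcode(s) in %s: %s", barcodes_path,
                        paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  if (anyDuplicated(genes))
    sl_validation_error("duplicate gene id(s) in %s", genes_path)

  pos <- read_positions(positions_path)
  missing <- setdiff(barcodes, pos$barcode)
  if (length(missing))
    sl_format_error("positions table %s is missing %d barcode(s), e.g. %s",
                    positions_path, length(missing), missing[1])
  pos <- pos[match(barcodes, pos$barcode), ]

  if (is.null(annotations)) {
    ann <- data.frame(spot_id = barcodes, sample_id = "S1", group = "g1",
                      stringsAsFactors = FALSE)
  } else {
    need <- c("spot_id", "sample_id", "group")
    if (!all(need %in% names(annotations)))
      sl_format_error("annotations need columns %s", paste(need, collapse = ", "))
    ann <- annotations[match(barcodes, annotations$spot_id), ]
    if (anyNA(ann$spot_id))
      sl_validation_error("annotations missing %d barcode(s)", sum(is.na(ann$spot_id)))
  }

  spot_dataset(counts = counts, gene_ids = genes, spot_ids = barcodes,
               array_row = pos$array_row, array_col = pos$array_col,
               sample_id = ann$sample_id, group = ann$group,
               cluster = ann$cluster %||% NULL,
               compartment = ann$compartment %||% NULL)
}

read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(pos) < 4L)
      sl_format_error("positions file %s needs >= 4 columns", path)
    names(pos)[1:4] <- c("barcode", "in_tissue", "array_row", "array_col")
  }
  need <- c("barcode", "array_row", "array_col")
  if (!all(need %in% names(pos)))
    sl_format_error("positions file %s lacks columns %s", path,
                    paste(setdiff(need, names(pos)), collapse = ", "))
  if (anyDuplicated(pos$barcode))
    sl_validation_error("duplicate barcode(s) in positions file %s", path)
  pos
}

#' Write a spot_dataset as a 10x triplet layout
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `positions.csv` and
#' `annotations.tsv` under `dir`. Read back with [read_10x_triplet()]; the
#' round trip is the identity on counts, coordinates and annotations.
#'
#' @param ds a `spot_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_10x_triplet <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "positions.csv", "annotations.tsv"))
  Matrix::writeMM(ds$counts, paths[1])
  writeLines(rownames(ds$counts), paths[2])
  writeLines(ds$spots$spot_id, paths[3])
  pos <- data.frame(barcode = ds$spots$spot_id, in_tissue = 1L,
                    array_row = ds$spots$array_row, array_col = ds$spots$array_col,
                    pxl_row = ds$spots$array_row * 100L,
                    pxl_col = ds$spots$array_col * 100L)
  utils::write.csv(pos, paths[4], row.names = FALSE, quote = FALSE)
  utils::write.table(ds$spots, paths[5], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are collapsed with a warning; a line with fewer than
#' three fields is a format error naming the line.
#'
#' @param path GMT file.
#' @return a named list of character vectors with attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) sl_format_error("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      sl_format_error("GMT line %d has %d field(s); need name, description, >=1 gene",
                      i, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': %d duplicate gene(s) collapsed",
                      fields[1], sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = desc, class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to "na").
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- descriptions[[nm]] %||% "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor reference table
#'
#' Tab-separated with columns `pair_id`, `ligand`, `receptor`; multi-subunit
#' complexes are comma-separated lists within a field. Every record needs at
#' least one ligand and one receptor gene; pair_ids must be unique.
#'
#' @param path TSV file.
#' @return data.frame with list-columns `ligand_genes`, `receptor_genes`.
#' @export
read_lr_reference <- function(path) {
  if (!file.exists(path)) sl_format_error("LR reference not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand", "receptor")
  if (!all(need %in% names(tab)))
    sl_format_error("LR reference %s lacks columns %s", path,
                    paste(setdiff(need, names(tab)), collapse = ", "))
  lr_reference(tab$pair_id, tab$ligand, tab$receptor)
}

#' Build a ligand-receptor reference in memory
#'
#' @param pair_id unique pair identifiers.
#' @param ligand,receptor gene symbols; comma-separated for complexes.
#' @return data.frame with list-columns `ligand_genes` / `receptor_genes`.
#' @export
lr_reference <- function(pair_id, ligand, receptor) {
  if (anyDuplicated(pair_id))
    sl_validation_error("duplicate pair_id(s): %s",
                        paste(unique(pair_id[duplicated(pair_id)]), collapse = ", "))
  split_genes <- function(x) {
    out <- strsplit(as.character(x), ",", fixed = TRUE)
    lapply(out, function(g) trimws(g[nzchar(trimws(g))]))
  }
  lg <- split_genes(ligand); rg <- split_genes(receptor)
  if (any(lengths(lg) == 0L) || any(lengths(rg) == 0L))
    sl_validation_error("every LR record needs >=1 ligand and >=1 receptor gene")
  out <- data.frame(pair_id = as.character(pair_id), stringsAsFactors = FALSE)
  out$ligand_genes <- lg
  out$receptor_genes <- rg
  out
}

#' Write a signaling network as a TSV edge list
#'
#' Emits a header plus one row per edge
#' (`sender_cluster, receiver_cluster, ligand, receptor, tf_module,
#' correlation`), preceded by commented run-metadata lines (`#key<TAB>json`)
#' carrying the config snapshot and seed so the file is self-describing.
#' [read_network()] reproduces the edge set exactly.
#'
#' @param network a `signaling_network` (see [run_interaction_analysis()]).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) sl_stop("spotlink_io_error",
                                              "cannot open %s for writing", path))
  on.exit(close(con))
  meta <- list(config = unclass(network$config %||% list()),
               seed = network$seed %||% NA,
               package_version = as.character(utils::packageVersion("spotlink")))
  writeLines(paste0("#metadata\t", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  edges <- network$edges
  cols <- c("sender_cluster", "receiver_cluster", "ligand", "receptor",
            "tf_module", "correlation")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(edges)) {
    body <- do.call(paste, c(lapply(cols, function(cc) {
      v <- edges[[cc]]
      if (is.numeric(v)) format(v, digits = 15) else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a signaling network written by write_network
#' @param path TSV produced by [write_network()].
#' @return a `signaling_network` with `edges` and `metadata`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) sl_format_error("network file not found: %s", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    meta <- jsonlite::fromJSON(sub("^#[^\t]*\t", "", lines[i]), simplifyVector = TRUE)
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  edges <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(rep("character", 5), "numeric"))
  structure(list(edges = edges, metadata = meta), class = "signaling_network")
}
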