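# Tabular model I/O: a TSV dialect mirroring a curation spreadsheet
# layout, with columns  id  name  equation  lb  ub  subsystem  genes
# and `# key: value` header comments for model-level metadata
# (biomass, gam, oxidation ids). Species molar masses, when present,
# travel in a companion species table.

#' Read a model from a reaction-table TSV
#'
#' @param path Path to the reaction TSV (columns `id`, `name`,
#'   `equation`, `lb`, `ub`, `subsystem`, `genes`; `#`-prefixed header
#'   comments may carry `biomass`, `gam`, `oxidation`, `exchange`
#'   metadata).
#' @param species_path Optional companion TSV with columns `id`,
#'   `name`, `compartment`, `molar_mass`.
#' @return A `metabolic_model`.
#' @export
read_table_model <- function(path, species_path = NULL) {
  lines <- readLines(path)
  meta <- parse_meta(lines)
  df <- read.delim(text = paste(lines[!startsWith(trimws(lines), "#")], collapse = "\n"),
                   sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "equation")
  if (!all(need %in% names(df)))
    abort(sprintf("%s: reaction table needs at least columns %s", path,
                  paste(need, collapse = ", ")))
  if (!nrow(df)) {
    rxns <- list()
  } else {
    rxns <- pmap(list(df$id, df$equation,
                      df$lb %||% rep(NA_real_, nrow(df)),
                      df$ub %||% rep(NA_real_, nrow(df)),
                      df$name %||% rep("", nrow(df)),
                      df$subsystem %||% rep("", nrow(df)),
                      df$genes %||% rep("", nrow(df))),
                 function(id, eq, lb, ub, nm, ss, gn) {
                   parse_equation(eq, id = id,
                                  lb = if (is.na(lb)) NULL else lb,
                                  ub = if (is.na(ub)) NULL else ub,
                                  name = ifelse(is.na(nm), "", nm),
                                  subsystem = ifelse(is.na(ss), "", ss),
                                  genes = ifelse(is.na(gn), "", gn))
                 })
  }
  species <- NULL
  if (!is.null(species_path) && file.exists(species_path))
    species <- as_tibble(read.delim(species_path, sep = "\t", stringsAsFactors = FALSE))
  metabolic_model(
    rxns, species = species,
    biomass_id = meta$biomass,
    exchange_ids = if (!is.null(meta$exchange)) split_ids(meta$exchange) else NULL,
    gam = if (!is.null(meta$gam)) as.numeric(meta$gam) else 25,
    oxidation_ids = if (!is.null(meta$oxidation)) split_ids(meta$oxidation) else character()
  )
}

parse_meta <- function(lines) {
  hdr <- grep("^#\\s*[A-Za-z_]+\\s*:", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    out[[tolower(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  out
}

split_ids <- function(x) trimws(strsplit(x, ",")[[1]])

#' Write a model as a reaction-table TSV
#'
#' @param model A `metabolic_model`.
#' @param path Output path for the reaction TSV.
#' @param species_path Optional path for the companion species table
#'   (written when any species has a molar mass).
#' @return `path`, invisibly.
#' @export
write_table_model <- function(model, path, species_path = NULL) {
  df <- tidy(model)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$biomass_id)) writeLines(sprintf("# biomass: %s", model$biomass_id), con)
  writeLines(sprintf("# gam: %g", model$gam), con)
  if (length(model$oxidation_ids))
    writeLines(sprintf("# oxidation: %s", paste(model$oxidation_ids, collapse = ",")), con)
  if (length(model$exchange_ids))
    writeLines(sprintf("# exchange: %s", paste(model$exchange_ids, collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(species_path) || any(!is.na(model$species$molar_mass))) {
    species_path <- species_path %||% sub("(\\.tsv)?$", "_species.tsv", path)
    write.table(model$species, species_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
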