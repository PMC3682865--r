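## The two-table on-disk store: an SQLite file with a chain-mapping
## table and an atomic property table. Boolean columns are declared
## BOOLEAN and restored to logical on read; missing experimental
## conditions are explicit NULLs. The schema version sits in the
## file's user_version pragma so the store keeps exactly two tables.

.STORE_VERSION <- 1L

.MAPPING_KEY <- c("pdb_id", "chain_index")
.ATOM_KEY <- c("pdb_id", "chain_index", "residue_index", "atom_name")

.sqlType <- function(col) {
  if (is.logical(col)) "BOOLEAN"
  else if (is.integer(col)) "INTEGER"
  else if (is.numeric(col)) "REAL"
  else "TEXT"
}

.createTable <- function(con, name, df, key) {
  cols <- vapply(names(df), function(nm)
    paste0('"', nm, '" ', .sqlType(df[[nm]])), character(1))
  sql <- paste0('CREATE TABLE "', name, '" (', paste(cols, collapse = ", "),
                ")")
  DBI::dbExecute(con, sql)
  DBI::dbExecute(con, paste0('CREATE UNIQUE INDEX "idx_', name, '" ON "',
                             name, '" (',
                             paste0('"', key, '"', collapse = ", "), ")"))
}

.checkKeys <- function(df, key, what) {
  if (!nrow(df)) return(invisible())
  kv <- do.call(paste, c(df[key], sep = "|"))
  dup <- unique(kv[duplicated(kv)])
  if (length(dup))
    stop("duplicate ", what, " key(s): ", paste(dup, collapse = "; "))
}

#' Write the two-table store
#'
#' @param mapping data.frame of chain-mapping records (one row per
#'   PDB-chain / accession pairing; needs pdb_id and chain_index).
#' @param atomsDf data.frame of atom shift records with feature
#'   columns (needs pdb_id, chain_index, residue_index, atom_name).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
storeWrite <- function(mapping, atomsDf, path) {
  miss <- setdiff(.MAPPING_KEY, names(mapping))
  if (length(miss)) stop("mapping table lacks: ", paste(miss, collapse = ", "))
  miss <- setdiff(.ATOM_KEY, names(atomsDf))
  if (length(miss)) stop("atom table lacks: ", paste(miss, collapse = ", "))
  .checkKeys(mapping, .MAPPING_KEY, "chain-mapping")
  .checkKeys(atomsDf, .ATOM_KEY, "atomic-property")
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  .createTable(con, "chain_mapping", mapping, .MAPPING_KEY)
  .createTable(con, "atomic_properties", atomsDf, .ATOM_KEY)
  if (nrow(mapping))
    DBI::dbAppendTable(con, "chain_mapping", mapping)
  if (nrow(atomsDf))
    DBI::dbAppendTable(con, "atomic_properties", atomsDf)
  DBI::dbExecute(con, paste0("PRAGMA user_version = ", .STORE_VERSION))
  invisible(path)
}

.booleanColumns <- function(con, table) {
  info <- DBI::dbGetQuery(con, paste0('PRAGMA table_info("', table, '")'))
  info$name[toupper(info$type) == "BOOLEAN"]
}

#' Read the two-table store
#'
#' Inverse of [storeWrite()]: boolean columns come back as logical,
#' NULLs as NA.
#'
#' @param path Store file path.
#' @return List with `mapping` and `atoms` data.frames and `version`.
#' @export
storeRead <- function(path) {
  if (!file.exists(path)) stop("no store at ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  tabs <- DBI::dbListTables(con)
  need <- c("chain_mapping", "atomic_properties")
  if (!all(need %in% tabs))
    stop("not a shift store (tables: ", paste(tabs, collapse = ", "), ")")
  readTab <- function(name) {
    df <- DBI::dbReadTable(con, name)
    for (bc in .booleanColumns(con, name)) df[[bc]] <- as.logical(df[[bc]])
    df
  }
  ver <- DBI::dbGetQuery(con, "PRAGMA user_version")[[1]]
  list(mapping = readTab("chain_mapping"),
       atoms = readTab("atomic_properties"), version = as.integer(ver))
}

#' Add a boolean filter column to the chain-mapping table
#'
#' Schema evolution for late filtering: the mapping table gains one
#' named boolean column; all pre-existing cells are untouched.
#'
#' @param path Store file path.
#' @param columnName New column name (collision is an error).
#' @param values Logical vector, one per mapping row (or length 1,
#'   recycled).
#' @return `path`, invisibly.
#' @export
addFilterColumn <- function(path, columnName, values) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  info <- DBI::dbGetQuery(con, 'PRAGMA table_info("chain_mapping")')
  if (columnName %in% info$name)
    stop("filter column '", columnName, "' already exists")
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", columnName))
    stop("invalid column name: ", columnName)
  n <- DBI::dbGetQuery(con, 'SELECT COUNT(*) AS n FROM "chain_mapping"')$n
  values <- as.logical(values)
  if (length(values) == 1L) values <- rep(values, n)
  if (length(values) != n)
    stop("need ", n, " values for column '", columnName, "', got ",
         length(values))
  DBI::dbExecute(con, paste0('ALTER TABLE "chain_mapping" ADD COLUMN "',
                             columnName, '" BOOLEAN'))
  if (n > 0) {
    rid <- DBI::dbGetQuery(con, 'SELECT rowid FROM "chain_mapping" ORDER BY rowid')$rowid
    for (i in seq_len(n))
      DBI::dbExecute(con, paste0('UPDATE "chain_mapping" SET "', columnName,
                                 '" = ? WHERE rowid = ?'),
                     params = list(as.integer(values[i]), rid[i]))
  }
  invisible(path)
}
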