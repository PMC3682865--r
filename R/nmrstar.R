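## Fault-tolerant NMRStar (2.1 / 3.1) chemical-shift reader plus a
## deterministic writer used by the fixture generator. Real deposition
## files are notoriously messy, so the reader recovers from stray
## tokens, duplicated save frames, non-numeric shift values and
## encoding glitches, counting every recovered anomaly in a parse
## report instead of failing.

.tokenizeStar <- function(lines) {
  toks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {            # multiline value block
      buf <- character(0)
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- c(buf, lines[i]); i <- i + 1L
      }
      toks[[length(toks) + 1L]] <- paste(buf, collapse = "\n")
      i <- i + 1L
      next
    }
    ln <- sub("(^|\\s)#.*$", "", ln)      # comments (quoted '#' not supported)
    if (nzchar(trimws(ln))) {
      m <- regmatches(ln, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", ln))[[1]]
      m <- sub("^['\"]", "", sub("['\"]$", "", m))
      toks <- c(toks, as.list(m))
    }
    i <- i + 1L
  }
  unlist(toks, use.names = FALSE)
}

## Walk the token stream into frames, each holding key-value pairs and
## loops (tags + raw data tokens). Content outside any save frame goes
## to a frame named "".
.starFrames <- function(tokens) {
  frames <- list()
  cur <- list(name = "", kv = list(), loops = list())
  i <- 1L
  n <- length(tokens)
  flush <- function() frames[[length(frames) + 1L]] <<- cur
  while (i <= n) {
    t <- tokens[i]
    if (grepl("^save_.+", t)) {
      flush(); cur <- list(name = sub("^save_", "", t), kv = list(),
                           loops = list())
      i <- i + 1L
    } else if (t == "save_") {
      flush(); cur <- list(name = "", kv = list(), loops = list())
      i <- i + 1L
    } else if (t == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(tokens[i], "_")) {
        tags <- c(tags, tokens[i]); i <- i + 1L
      }
      dat <- character(0)
      while (i <= n && !tokens[i] %in% c("stop_", "loop_") &&
             !grepl("^save_", tokens[i]) &&
             !(startsWith(tokens[i], "_") && FALSE)) {
        if (tokens[i] == "stop_") break
        dat <- c(dat, tokens[i]); i <- i + 1L
      }
      if (i <= n && tokens[i] == "stop_") i <- i + 1L
      cur$loops[[length(cur$loops) + 1L]] <- list(tags = tags, data = dat)
    } else if (startsWith(t, "_")) {
      val <- if (i + 1L <= n && !startsWith(tokens[i + 1L], "_") &&
                 !tokens[i + 1L] %in% c("loop_", "stop_", "save_"))
        tokens[i + 1L] else NA_character_
      cur$kv[[t]] <- val
      i <- i + (if (is.na(val)) 1L else 2L)
    } else {
      i <- i + 1L                          # stray top-level token
    }
  }
  flush()
  frames
}

.isNum <- function(x) !is.na(suppressWarnings(as.numeric(x)))
.isInt <- function(x) grepl("^-?[0-9]+$", x)

## Row-resynchronizing extraction of a shift loop: rows whose structural
## columns fail validation cause single-token drops (stray_token) until
## alignment is recovered.
.parseShiftLoop <- function(loop, dialect, report) {
  tags <- loop$tags
  k <- length(tags)
  low <- tolower(tags)
  idx <- function(suffixes) {
    for (s in suffixes) {
      j <- which(endsWith(low, tolower(s)))
      if (length(j)) return(j[1])
    }
    NA_integer_
  }
  if (dialect == "3.1") {
    iSeq <- idx(c(".seq_id", ".comp_index_id"))
    iRes <- idx(".comp_id"); iAtom <- idx(".atom_id")
    iVal <- which(endsWith(low, ".val") & !endsWith(low, ".val_err"))[1]
    iAmb <- idx(".ambiguity_code")
    iEnt <- idx(c(".entity_assembly_id", ".entity_id"))
  } else {
    iSeq <- idx("_residue_seq_code"); iRes <- idx("_residue_label")
    iAtom <- idx("_atom_name"); iVal <- idx("_chem_shift_value")
    iAmb <- idx("_chem_shift_ambiguity_code"); iEnt <- NA_integer_
  }
  d <- loop$data
  rows <- list()
  i <- 1L
  while (i + k - 1L <= length(d)) {
    row <- d[i:(i + k - 1L)]
    okStruct <- .isInt(row[iSeq]) &&
      grepl("^[A-Za-z]{1,3}[0-9]?$", row[iRes]) &&
      grepl("^[A-Za-z][A-Za-z0-9']{0,4}$|^[0-9][A-Za-z][A-Za-z0-9]{0,3}$",
            row[iAtom])
    if (!okStruct) {
      report$anomalies["stray_token"] <- report$anomalies["stray_token"] + 1L
      i <- i + 1L
      next
    }
    if (!.isNum(row[iVal])) {
      report$anomalies["nonnumeric_shift"] <-
        report$anomalies["nonnumeric_shift"] + 1L
      i <- i + k
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      entity = if (!is.na(iEnt) && .isInt(row[iEnt]))
        as.integer(row[iEnt]) else 1L,
      residue_index = as.integer(row[iSeq]),
      residue_type = toupper(row[iRes]),
      atom_name = toupper(row[iAtom]),
      shift = as.numeric(row[iVal]),
      ambiguity = if (!is.na(iAmb) && .isInt(row[iAmb]))
        as.integer(row[iAmb]) else NA_integer_,
      stringsAsFactors = FALSE)
    i <- i + k
  }
  if (i <= length(d))
    report$anomalies["stray_token"] <- report$anomalies["stray_token"] +
      (length(d) - i + 1L)
  list(shifts = if (length(rows)) do.call(rbind, rows) else NULL,
       report = report)
}

.extractConditions <- function(frames) {
  cond <- list(temperature = NA_real_, ph = NA_real_, pressure = NA_real_,
               solvent = NA_character_, spectrometer = NA_character_)
  for (fr in frames) {
    for (key in names(fr$kv)) {
      lk <- tolower(key)
      v <- fr$kv[[key]]
      if (is.na(v) || v %in% c(".", "?")) next
      if (grepl("solvent_system$", lk)) cond$solvent <- v
      if (grepl("spectrometer.*model$|\\.model$", lk) &&
          grepl("spectrometer", tolower(fr$name)) || grepl("^_nmr_spectrometer\\.model$", lk))
        cond$spectrometer <- v
    }
    for (lp in fr$loops) {
      low <- tolower(lp$tags)
      iT <- which(grepl("variable.type$|variable_type$", low))[1]
      iV <- which(grepl("variable.val$|variable_value$|variable\\.val$", low) &
                  !grepl("units|err", low))[1]
      if (is.na(iT) || is.na(iV)) next
      k <- length(lp$tags)
      d <- lp$data
      nr <- length(d) %/% k
      for (r in seq_len(nr)) {
        type <- tolower(d[(r - 1L) * k + iT])
        val <- d[(r - 1L) * k + iV]
        if (!.isNum(val)) next
        val <- as.numeric(val)
        if (grepl("temp", type)) cond$temperature <- val
        else if (type == "ph") cond$ph <- val
        else if (grepl("press", type)) cond$pressure <- val
      }
    }
  }
  cond
}

#' Parse an NMRStar chemical-shift file
#'
#' Accepts both the 2.1 and the 3.1 dialect and tolerates common file
#' corruptions, which are counted per category in the returned parse
#' report: `stray_token` (token dropped to re-synchronize a loop row),
#' `duplicate_frame` (extra assigned-shift frame ignored),
#' `nonnumeric_shift` (shift row dropped), `encoding_glitch`
#' (non-ASCII bytes removed), `duplicate_row` (repeated atom kept once).
#' A file without any recognizable shift loop is a fatal error.
#'
#' @param path Path to an NMRStar file.
#' @return A list with elements `shifts` (data.frame: entity,
#'   residue_index, residue_type, atom_name, shift, ambiguity),
#'   `conditions` (temperature K, ph, pressure atm, solvent,
#'   spectrometer; NA when absent) and `report` (anomaly counts,
#'   dialect, fatal flag).
#' @export
parseNMRStar <- function(path) {
  if (!file.exists(path)) stop("cannot read NMRStar file: ", path)
  raw <- readLines(path, warn = FALSE)
  report <- list(anomalies = c(stray_token = 0L, duplicate_frame = 0L,
                               nonnumeric_shift = 0L, encoding_glitch = 0L,
                               duplicate_row = 0L),
                 dialect = NA_character_, fatal = FALSE)
  clean <- iconv(raw, from = "UTF-8", to = "ASCII", sub = "")
  bad <- is.na(clean)
  clean[bad] <- iconv(raw[bad], from = "latin1", to = "ASCII", sub = "")
  clean[is.na(clean)] <- ""
  nGlitch <- sum(clean != raw, na.rm = TRUE) + sum(is.na(clean))
  report$anomalies["encoding_glitch"] <- nGlitch

  tokens <- .tokenizeStar(clean)
  frames <- .starFrames(tokens)

  isShiftLoop <- function(lp) {
    low <- tolower(lp$tags)
    any(grepl("^_atom_chem_shift\\.", low)) ||
      any(low == "_chem_shift_value")
  }
  shiftLoops <- list()
  for (fr in frames) for (lp in fr$loops)
    if (isShiftLoop(lp)) shiftLoops[[length(shiftLoops) + 1L]] <- lp
  if (!length(shiftLoops)) {
    report$fatal <- TRUE
    stop("no chemical-shift loop found in ", path)
  }
  if (length(shiftLoops) > 1L)
    report$anomalies["duplicate_frame"] <- length(shiftLoops) - 1L
  lp <- shiftLoops[[1L]]
  dialect <- if (any(grepl("^_atom_chem_shift\\.", tolower(lp$tags))))
    "3.1" else "2.1"
  report$dialect <- dialect

  out <- .parseShiftLoop(lp, dialect, report)
  report <- out$report
  shifts <- out$shifts
  if (is.null(shifts)) {
    report$fatal <- TRUE
    stop("shift loop in ", path, " contains no readable rows")
  }
  key <- paste(shifts$entity, shifts$residue_index, shifts$atom_name)
  dup <- duplicated(key)
  if (any(dup)) {
    report$anomalies["duplicate_row"] <- sum(dup)
    shifts <- shifts[!dup, , drop = FALSE]
  }
  rownames(shifts) <- NULL
  list(shifts = shifts, conditions = .extractConditions(frames),
       report = report)
}

#' Write a chemical-shift list as an NMRStar file
#'
#' Deterministic writer for both dialects; used to build test fixtures
#' and to round-trip parsed data.
#'
#' @param shifts data.frame with columns entity, residue_index,
#'   residue_type, atom_name, shift, and optionally ambiguity.
#' @param path Output path.
#' @param dialect `"3.1"` or `"2.1"`.
#' @param conditions Named list (temperature, ph, pressure, solvent,
#'   spectrometer); NA entries are written as ".".
#' @param entryId Entry accession string.
#' @return `path`, invisibly.
#' @export
writeNMRStar <- function(shifts, path, dialect = c("3.1", "2.1"),
                         conditions = list(temperature = 298, ph = 7.0,
                                           pressure = 1.0,
                                           solvent = "90% H2O/10% D2O",
                                           spectrometer = "AVANCE600"),
                         entryId = "SF0001") {
  dialect <- match.arg(dialect)
  if (is.null(shifts$ambiguity)) shifts$ambiguity <- 1L
  amb <- ifelse(is.na(shifts$ambiguity), ".",
                as.character(shifts$ambiguity))
  q <- function(x) if (is.na(x)) "." else if (grepl("\\s", x))
    paste0("'", x, "'") else x
  num <- function(x) if (is.null(x) || is.na(x)) "." else
    format(x, trim = TRUE)
  atype <- substr(sub("^[0-9]+", "", shifts$atom_name), 1, 1)
  L <- c(paste0("data_", entryId), "")
  if (dialect == "3.1") {
    L <- c(L,
      "save_sample_1",
      "   _Sample.Sf_category  sample",
      paste0("   _Sample.Solvent_system  ", q(conditions$solvent)),
      "save_", "",
      "save_sample_conditions_1",
      "   _Sample_condition_list.Sf_category  sample_conditions",
      "   loop_",
      "      _Sample_condition_variable.Type",
      "      _Sample_condition_variable.Val",
      "      _Sample_condition_variable.Val_units",
      "",
      paste0("      temperature ", num(conditions$temperature), " K"),
      paste0("      pH ", num(conditions$ph), " pH"),
      paste0("      pressure ", num(conditions$pressure), " atm"),
      "   stop_",
      "save_", "",
      "save_spectrometer_1",
      "   _NMR_spectrometer.Sf_category  NMR_spectrometer",
      paste0("   _NMR_spectrometer.Model  ", q(conditions$spectrometer)),
      "save_", "",
      "save_assigned_chem_shift_list_1",
      "   _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
      "   loop_",
      "      _Atom_chem_shift.ID",
      "      _Atom_chem_shift.Entity_assembly_ID",
      "      _Atom_chem_shift.Seq_ID",
      "      _Atom_chem_shift.Comp_ID",
      "      _Atom_chem_shift.Atom_ID",
      "      _Atom_chem_shift.Atom_type",
      "      _Atom_chem_shift.Val",
      "      _Atom_chem_shift.Ambiguity_code",
      "",
      sprintf("      %d %d %d %s %s %s %.3f %s",
              seq_len(nrow(shifts)), shifts$entity, shifts$residue_index,
              shifts$residue_type, shifts$atom_name, atype, shifts$shift,
              amb),
      "   stop_",
      "save_")
  } else {
    L <- c(L,
      "save_sample_conditions",
      "   _Saveframe_category  sample_conditions",
      "   loop_",
      "      _Variable_type",
      "      _Variable_value",
      "",
      paste0("      temperature ", num(conditions$temperature)),
      paste0("      pH ", num(conditions$ph)),
      paste0("      pressure ", num(conditions$pressure)),
      "   stop_",
      paste0("   _Solvent_system  ", q(conditions$solvent)),
      "save_", "",
      "save_assigned_chemical_shifts",
      "   _Saveframe_category  assigned_chemical_shifts",
      paste0("   _NMR_spectrometer.Model  ", q(conditions$spectrometer)),
      "   loop_",
      "      _Atom_shift_assign_ID",
      "      _Residue_seq_code",
      "      _Residue_label",
      "      _Atom_name",
      "      _Atom_type",
      "      _Chem_shift_value",
      "      _Chem_shift_ambiguity_code",
      "",
      sprintf("      %d %d %s %s %s %.3f %s",
              seq_len(nrow(shifts)), shifts$residue_index,
              shifts$residue_type, shifts$atom_name, atype, shifts$shift,
              amb),
      "   stop_",
      "save_")
  }
  writeLines(L, path)
  invisible(path)
}
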