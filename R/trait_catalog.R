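#' @importFrom rlang .data
#' @importFrom stats sd setNames
#' @importFrom utils head
NULL

# Canonical month handling: calendar indices 1..12, Jan = 1.
MONTH_ABB <- c("jan", "feb", "mar", "apr", "may", "jun",
               "jul", "aug", "sep", "oct", "nov", "dec")

PROVENANCE_LEVELS <- c("native", "exotic", "unknown")
FUNCTIONAL_GROUPS <- c("C3_graminoid", "C4_graminoid", "forb", "legume",
                       "woody", "other")
LIFEFORMS <- c("herbaceous", "tree_seedling", "genus_only_placeholder")

#' Parse a flowering-interval string into a set of month indices
#'
#' Floras report flowering time as month lists ("June, July, and August"),
#' abbreviations ("Jun; Jul"), integers, or ranges ("May-Aug"); ranges may
#' wrap the year end ("Nov-Feb" covers November through February). This
#' parser turns any of those into the set of calendar month indices covered.
#'
#' @param text A non-empty character scalar. Tokens may be separated by
#'   commas, semicolons, slashes, whitespace or the word "and"; a range is
#'   two month tokens joined by a hyphen, en dash, em dash, "to" or
#'   "through". Ranges are inclusive and may wrap December into January.
#' @return An integer vector of distinct month indices in 1..12, sorted in
#'   calendar order.
#' @examples
#' parse_flowering_interval("June, July, and August")  # 6 7 8
#' parse_flowering_interval("Nov-Feb")                 # 1 2 11 12
#' @export
parse_flowering_interval <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("flowering interval must be a non-empty string", call. = FALSE)
  }
  txt <- tolower(text)
  # normalise en/em dashes and the words 'to'/'through' to a range marker
  txt <- gsub("–|—", "-", txt)
  txt <- gsub("\\b(to|through|thru)\\b", "-", txt)
  txt <- gsub("\\band\\b", " ", txt)
  txt <- gsub("[[:space:]]*-[[:space:]]*", "-", txt)
  tokens <- strsplit(txt, "[,;/[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("flowering interval '", text, "' contains no month tokens",
         call. = FALSE)
  }
  months <- integer(0)
  for (tok in tokens) {
    if (grepl("-", tok, fixed = TRUE)) {
      ends <- strsplit(tok, "-+")[[1]]
      ends <- ends[nzchar(ends)]
      if (length(ends) != 2L) {
        stop("cannot parse flowering range token '", tok, "' in '", text,
             "'", call. = FALSE)
      }
      from <- .parse_month_token(ends[1], text)
      to <- .parse_month_token(ends[2], text)
      months <- c(months, .expand_month_range(from, to))
    } else {
      months <- c(months, .parse_month_token(tok, text))
    }
  }
  months <- sort(unique(months))
  if (length(months) == 0L) {
    stop("flowering interval '", text, "' yields no months", call. = FALSE)
  }
  months
}

.parse_month_token <- function(tok, context) {
  tok <- gsub("[.]", "", trimws(tok))
  if (grepl("^[0-9]+$", tok)) {
    m <- as.integer(tok)
    if (m >= 1L && m <= 12L) return(m)
    stop("month index '", tok, "' out of range in '", context, "'",
         call. = FALSE)
  }
  hit <- match(substr(tok, 1L, 3L), MONTH_ABB)
  # require the token to be a prefix-consistent month name ("ju" ambiguous)
  if (!is.na(hit) && nchar(tok) >= 3L &&
      startsWith(.month_name(hit), tok)) {
    return(hit)
  }
  stop("unrecognised month token '", tok, "' in '", context, "'",
       call. = FALSE)
}

.month_name <- function(i) tolower(month.name[i])

.expand_month_range <- function(from, to) {
  if (from <= to) from:to else c(from:12L, 1L:to)
}

#' Serialise a month set to its canonical string form
#'
#' Inverse of [parse_flowering_interval()]: produces a semicolon-separated
#' list of three-letter month abbreviations in calendar order, so that
#' parse -> serialise -> parse round-trips exactly.
#'
#' @param months Integer vector of month indices in 1..12.
#' @return A character scalar such as `"Jun;Jul;Aug"`.
#' @export
format_flowering_months <- function(months) {
  months <- sort(unique(as.integer(months)))
  stopifnot(all(months >= 1L & months <= 12L), length(months) >= 1L)
  paste(month.abb[months], collapse = ";")
}

#' Load and validate a species trait catalog
#'
#' Reads a trait CSV with columns `taxon, flowering_months, provenance,
#' functional_group, lifeform, source` (header required, UTF-8).
#' `flowering_months` holds semicolon-separated month tokens or a range
#' string, parsed with [parse_flowering_interval()]. Taxa identified only to
#' genus (`lifeform = "genus_only_placeholder"`) and tree seedlings are kept
#' in the catalog but flagged `includable = FALSE`, so the downstream
#' exclusion rule lives in one place. Rows that fail validation (other than
#' a duplicated taxon, which aborts) are dropped with a warning.
#'
#' @param path Path to the trait CSV.
#' @return A tibble with one row per taxon: `taxon`, `flowering_months`
#'   (list-column of integer month sets), `provenance`, `functional_group`,
#'   `lifeform`, `source`, `includable`.
#' @export
load_trait_catalog <- function(path) {
  required <- c("taxon", "flowering_months", "provenance",
                "functional_group", "lifeform")
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("trait catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  build_trait_catalog(raw)
}

#' Build a trait catalog from an in-memory data frame
#'
#' @param df Data frame with the trait CSV columns; `flowering_months` may
#'   be either strings (parsed) or a list-column of integer month sets.
#' @return Validated catalog tibble (see [load_trait_catalog()]).
#' @export
build_trait_catalog <- function(df) {
  df <- tibble::as_tibble(df)
  dup <- df$taxon[duplicated(df$taxon)]
  if (length(dup) > 0L) {
    stop("duplicate taxon in trait catalog: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (is.list(df$flowering_months)) {
    months <- lapply(df$flowering_months,
                     function(m) sort(unique(as.integer(m))))
  } else {
    months <- lapply(df$flowering_months, function(s) {
      tryCatch(parse_flowering_interval(s), error = function(e) e)
    })
  }
  bad_parse <- vapply(months, inherits, logical(1), what = "error")
  bad_prov <- !(df$provenance %in% PROVENANCE_LEVELS)
  bad_fg <- !(df$functional_group %in% FUNCTIONAL_GROUPS)
  bad_lf <- !(df$lifeform %in% LIFEFORMS)
  bad <- bad_parse | bad_prov | bad_fg | bad_lf
  if (any(bad)) {
    msgs <- vapply(which(bad), function(i) {
      why <- c(
        if (bad_parse[i]) conditionMessage(months[[i]]),
        if (bad_prov[i]) paste0("provenance '", df$provenance[i], "'"),
        if (bad_fg[i]) paste0("functional_group '", df$functional_group[i], "'"),
        if (bad_lf[i]) paste0("lifeform '", df$lifeform[i], "'"))
      paste0(df$taxon[i], " (", paste(why, collapse = "; "), ")")
    }, character(1))
    warning("dropping ", sum(bad), " invalid trait row(s): ",
            paste(msgs, collapse = " | "), call. = FALSE)
  }
  keep <- !bad
  cat <- tibble::tibble(
    taxon = df$taxon[keep],
    flowering_months = months[keep],
    provenance = df$provenance[keep],
    functional_group = df$functional_group[keep],
    lifeform = df$lifeform[keep],
    source = if ("source" %in% names(df)) df$source[keep] else NA_character_
  )
  cat$includable <- !(cat$lifeform %in% c("genus_only_placeholder",
                                          "tree_seedling"))
  empty <- cat$includable &
    vapply(cat$flowering_months, length, integer(1)) == 0L
  if (any(empty)) {
    stop("includable taxa with empty flowering months: ",
         paste(cat$taxon[empty], collapse = ", "), call. = FALSE)
  }
  gram <- cat$functional_group %in% c("C3_graminoid", "C4_graminoid")
  message("trait catalog: loaded ", nrow(cat), " taxa (",
          sum(!cat$includable), " flagged non-includable, ",
          sum(gram), " graminoids); skipped ", sum(bad), " invalid row(s)")
  cat
}

#' 0/1 flowering weight of a species in a month
#'
#' The monthly weight at the heart of the flowering-potential statistic:
#' a species contributes its relative cover to a month's FP iff its flora
#' reports it in flower that month.
#'
#' @param trait A one-row slice of a trait catalog, or any list with a
#'   `flowering_months` element; alternatively a bare integer vector of
#'   flowering month indices.
#' @param month Month index in 1..12.
#' @return `1L` if the species flowers in `month`, else `0L`.
#' @export
is_flowering <- function(trait, month) {
  stopifnot(length(month) == 1L, month %in% 1:12)
  fm <- if (is.numeric(trait)) {
    as.integer(trait)
  } else if (!is.null(trait$flowering_months)) {
    m <- trait$flowering_months
    if (is.list(m)) m <- m[[1L]]
    as.integer(m)
  } else {
    stop("'trait' must carry flowering months", call. = FALSE)
  }
  as.integer(month %in% fm)
}

#' Species-by-month 0/1 flowering weight matrix
#'
#' @param catalog Trait catalog tibble.
#' @return Numeric matrix, rows named by taxon, 12 columns (Jan..Dec), with
#'   entry 1 where the taxon flowers that month.
#' @export
flowering_weight_matrix <- function(catalog) {
  W <- matrix(0, nrow(catalog), 12L,
              dimnames = list(catalog$taxon, month.abb))
  for (i in seq_len(nrow(catalog))) {
    W[i, catalog$flowering_months[[i]]] <- 1
  }
  W
}

#' Write a trait catalog back to its CSV dialect
#'
#' @param catalog Trait catalog tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_catalog <- function(catalog, path) {
  out <- catalog
  out$flowering_months <- vapply(catalog$flowering_months,
                                 format_flowering_months, character(1))
  out$includable <- NULL
  readr::write_csv(out, path)
  invisible(path)
}
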