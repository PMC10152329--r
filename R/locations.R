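# Location detection: Canadian/US postal codes found by regular
# expressions in the raw text and place names matched in the token stream,
# both resolved against an offline gazetteer (forward-sortation-area
# prefixes for Canadian codes, full 5-digit ZIPs for US codes, lemmatized
# names for cities and provinces). Resolved mentions become proportional
# per-document city and province weights.

.ca_postal_re <- "(?<![A-Za-z0-9])[A-Za-z][0-9][A-Za-z] ?[0-9][A-Za-z][0-9](?![A-Za-z0-9])"
.us_zip_re <- "(?<![A-Za-z0-9-])[0-9]{5}(-[0-9]{4})?(?![A-Za-z0-9])"

#' Read an offline gazetteer table
#'
#' CSV with columns `kind` (`postal_prefix`, `zip` or `name`), `key`
#' (3-character forward sortation area, 5-digit ZIP, or place name),
#' `city` (may be empty for province-level names) and `province`. Within a
#' table each city maps to one province; for homonymous names the first
#' entry wins and later ones are dropped with a message.
#'
#' @param path CSV path.
#' @return object of class `ndkg_gazetteer`.
#' @export
read_gazetteer <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("kind", "key", "city", "province")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ndkg("gazetteer missing column(s): ", paste(miss, collapse = ", "))
  bad <- !df$kind %in% c("postal_prefix", "zip", "name")
  if (any(bad)) stop_ndkg("unknown gazetteer kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  df$city[!nzchar(df$city)] <- NA_character_
  city_prov <- unique(df[!is.na(df$city), c("city", "province")])
  dup_city <- unique(city_prov$city[duplicated(city_prov$city)])
  if (length(dup_city)) {
    message("gazetteer: homonymous city name(s), first entry wins: ",
            paste(dup_city, collapse = ", "))
    keep <- !(df$city %in% dup_city & duplicated(paste(df$kind, df$city)))
    df <- df[keep | is.na(df$city), , drop = FALSE]
  }
  dupkey <- duplicated(paste(df$kind, toupper(df$key)))
  df <- df[!dupkey, , drop = FALSE]
  structure(list(table = df), class = "ndkg_gazetteer")
}

#' Extract postal codes from raw text
#'
#' Matches Canadian postal codes (letter-digit-letter, optional space,
#' digit-letter-digit, case-insensitive) and US ZIP codes (5 digits with
#' optional -4 extension) at word boundaries; longer digit runs are not
#' ZIPs.
#'
#' @param text raw (pre-tokenization) document text.
#' @return character vector of matched code strings, in order of appearance.
#' @export
extract_postal_codes <- function(text) {
  m1 <- regmatches(text, gregexpr(.ca_postal_re, text, perl = TRUE))[[1]]
  m2 <- regmatches(text, gregexpr(.us_zip_re, text, perl = TRUE))[[1]]
  c(m1, m2)
}

#' Resolve a postal code against the gazetteer
#'
#' Canadian codes resolve by their 3-character forward-sortation-area
#' prefix, US ZIPs by the full 5 digits. Unresolvable codes return NULL
#' with a message.
#'
#' @param code one postal-code string from [extract_postal_codes()].
#' @param gaz an `ndkg_gazetteer`.
#' @return list(city, province) or NULL.
#' @export
resolve_postal <- function(code, gaz) {
  tab <- gaz$table
  code <- toupper(gsub(" ", "", code))
  row <- if (grepl("^[0-9]", code)) {
    tab[tab$kind == "zip" & tab$key == substr(code, 1, 5), , drop = FALSE]
  } else {
    tab[tab$kind == "postal_prefix" & toupper(tab$key) == substr(code, 1, 3), , drop = FALSE]
  }
  if (!nrow(row)) {
    message("unresolved postal code: ", code)
    return(NULL)
  }
  list(city = row$city[1], province = row$province[1])
}

# Compiled name matcher for the gazetteer's place names, reusing the
# lexicon machinery so names meet documents in lemma space.
.gaz_matcher <- function(gaz, stops) {
  names_tab <- gaz$table[gaz$table$kind == "name", , drop = FALSE]
  if (!nrow(names_tab)) return(NULL)
  entries <- data.frame(
    surface = names_tab$key,
    canonical = paste0(ifelse(is.na(names_tab$city), "", names_tab$city), "\r",
                       names_tab$province),
    vocab = "LOCATION",
    stringsAsFactors = FALSE
  )
  suppressWarnings(compile_lexicon(entries, stops))
}

#' Detect location mentions in one document
#'
#' Combines the postal-code channel (regular expressions on the raw text,
#' resolved via the gazetteer) and the place-name channel (gazetteer names
#' matched in the token stream). Each resolved mention contributes one row.
#'
#' @param text raw document text.
#' @param gaz an `ndkg_gazetteer`.
#' @param stops stop list (must match the corpus preprocessing).
#' @param doc_id carried into the result.
#' @return data frame `doc_id`, `city` (NA for province-level mentions),
#'   `province`, `channel`.
#' @export
detect_locations <- function(text, gaz, stops = ndkg_stopwords(),
                             doc_id = NA_character_) {
  rows <- list()
  for (code in extract_postal_codes(text)) {
    r <- resolve_postal(code, gaz)
    if (!is.null(r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc_id, city = r$city, province = r$province,
        channel = "postal", stringsAsFactors = FALSE)
    }
  }
  matcher <- .gaz_matcher(gaz, stops)
  if (!is.null(matcher)) {
    ts <- preprocess(text, stops, doc_id = doc_id)
    m <- match_entities(ts, matcher)
    if (nrow(m)) {
      parts <- strsplit(m$canonical, "\r", fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc_id,
        city = vapply(parts, function(p) if (nzchar(p[1])) p[1] else NA_character_, character(1)),
        province = vapply(parts, `[`, character(1), 2),
        channel = "name", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(), city = character(),
                      province = character(), channel = character()))
  }
  do.call(rbind, rows)
}

#' Proportional location weights for one document
#'
#' City weights are mention proportions over the document's city mentions;
#' province weights are proportions over its province mentions (a province
#' inferred from a city's resolution counts once in the province pool).
#' Each pool sums to 1 when non-empty.
#'
#' @param mentions data frame from [detect_locations()] (one document).
#' @return list of class `ndkg_locweights`: named numeric vectors `city`
#'   and `province`, plus `city_province` (named map city -> province).
#' @export
location_weights <- function(mentions) {
  city_m <- mentions$city[!is.na(mentions$city)]
  prov_m <- mentions$province[!is.na(mentions$province)]
  cw <- if (length(city_m)) table(city_m) / length(city_m) else NULL
  pw <- if (length(prov_m)) table(prov_m) / length(prov_m) else NULL
  cp <- unique(mentions[!is.na(mentions$city), c("city", "province")])
  structure(
    list(city = if (is.null(cw)) numeric() else stats::setNames(as.numeric(cw), names(cw)),
         province = if (is.null(pw)) numeric() else stats::setNames(as.numeric(pw), names(pw)),
         city_province = stats::setNames(cp$province, cp$city)),
    class = "ndkg_locweights"
  )
}
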