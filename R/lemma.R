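# Dictionary-based English lemmatizer in the WordNet "morphy" style:
# an irregular-form table consulted first, then suffix-detachment rules
# whose candidates are validated against a base-form dictionary. The same
# lemmatizer is used for documents, lexicon surface forms, gazetteer place
# names and queries, so surface forms always meet in lemma space.

.lemma_irregular <- c(
  children = "child", men = "man", women = "woman", feet = "foot",
  teeth = "tooth", mice = "mouse", geese = "goose", people = "person",
  lives = "life", selves = "self", leaves = "leaf", knives = "knife",
  wives = "wife", halves = "half",
  ran = "run", went = "go", gone = "go", goes = "go", made = "make",
  said = "say", says = "say", saw = "see", seen = "see", took = "take",
  taken = "take", came = "come", gave = "give", given = "give",
  got = "get", gotten = "get", felt = "feel", found = "find",
  kept = "keep", knew = "know", known = "know", met = "meet",
  paid = "pay", sat = "sit", spoke = "speak", spoken = "speak",
  stood = "stand", taught = "teach", thought = "think", told = "tell",
  understood = "understand", wrote = "write", written = "write",
  grew = "grow", grown = "grow", held = "hold", lost = "lose",
  meant = "mean", sent = "send", spent = "spend", built = "build",
  bought = "buy", brought = "bring", caught = "catch", chose = "choose",
  chosen = "choose", dealt = "deal", drew = "draw", drawn = "draw",
  ate = "eat", eaten = "eat", fell = "fall", fallen = "fall",
  heard = "hear", hit = "hit", hits = "hit", led = "lead", read = "read",
  slept = "sleep", spat = "spit", began = "begin", begun = "begin",
  broke = "break", broken = "break", spat = "spit", sought = "seek",
  was = "be", were = "be", is = "be", are = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have",
  does = "do", did = "do", doing = "do", done = "do"
)

# Base forms used to validate candidates produced by the suffix rules
# (notably silent-e restoration after stripping -ing/-ed). Deliberately
# small: validation only has to disambiguate between candidates, and an
# unvalidated fall-back rule still yields a deterministic lemma.
.lemma_base <- c(
  "make", "take", "use", "care", "have", "give", "live", "come", "write",
  "provide", "create", "manage", "include", "involve", "require",
  "service", "issue", "note", "share", "change", "close", "move", "name",
  "place", "raise", "reduce", "release", "save", "serve", "store",
  "type", "value", "time", "guide", "range", "age", "schedule",
  "practice", "engage", "measure", "improve", "increase", "decrease",
  "describe", "arrange", "operate", "locate", "educate", "communicate",
  "participate", "celebrate", "evaluate", "facilitate", "navigate",
  "organize", "recognize", "challenge", "encourage", "experience",
  "exercise", "advise", "advocate", "compare", "complete", "continue",
  "decide", "define", "determine", "examine", "explore", "promote",
  "receive", "relate", "remove", "resolve", "respond", "struggle",
  "fall", "tell", "call", "miss", "pass", "add", "roll", "spell",
  "press", "stress", "access", "discuss", "address", "dress", "guess",
  "cross", "assess", "fill", "skill", "will", "spill", "sell", "small",
  "run", "sit", "set", "plan", "stop", "swim", "begin", "refer", "occur",
  "child", "behavior", "school", "support", "program", "family",
  "parent", "therapy", "community", "resource", "need", "help", "learn",
  "play", "speak", "sleep", "read", "teach", "train", "work", "develop",
  "assist", "fund", "house", "base", "focus"
)

.double_ok <- c("b", "d", "g", "m", "n", "p", "r", "t")

.lemma_one <- function(w, irregular, base) {
  hit <- irregular[[w]]
  if (!is.null(hit) && !is.na(hit)) return(hit)
  n <- nchar(w)
  in_base <- function(x) x %in% base
  # noun rules
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 4 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
  for (suf in c("ches", "shes", "xes", "zes")) {
    if (n > nchar(suf) && endsWith(w, suf)) return(substr(w, 1, n - 2))
  }
  if (n > 3 && endsWith(w, "s") &&
      !endsWith(w, "ss") && !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  # verb rules: -ied, -ing, -ed with silent-e restoration and consonant
  # de-doubling decided by dictionary lookup, then by heuristic
  if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
  for (suf in c("ing", "ed")) {
    if (n > nchar(suf) + 2 && endsWith(w, suf)) {
      stem <- substr(w, 1, n - nchar(suf))
      m <- nchar(stem)
      dedoubled <- if (m > 2 && substr(stem, m, m) == substr(stem, m - 1, m - 1) &&
                       !grepl("[aeiou]", substr(stem, m, m))) {
        substr(stem, 1, m - 1)
      } else NA_character_
      if (in_base(stem)) return(stem)
      if (in_base(paste0(stem, "e"))) return(paste0(stem, "e"))
      if (!is.na(dedoubled) && in_base(dedoubled)) return(dedoubled)
      if (!is.na(dedoubled) && substr(stem, m, m) %in% .double_ok) {
        return(dedoubled)
      }
      return(stem)
    }
  }
  w
}

#' Lemmatize lowercase tokens
#'
#' Dictionary-based English lemmatization (noun and verb forms): irregular
#' forms are looked up in a built-in table, regular inflections are reduced
#' by suffix rules validated against a base-form dictionary. Idempotent:
#' `lemmatize(lemmatize(x)) == lemmatize(x)`.
#'
#' @param tokens character vector of lowercase tokens.
#' @param extra optional named character vector of additional
#'   `inflected = lemma` pairs, consulted before the built-in table.
#' @return character vector of lemmas, same length as `tokens`.
#' @export
lemmatize <- function(tokens, extra = NULL) {
  irregular <- as.list(.lemma_irregular)
  if (!is.null(extra)) irregular[names(extra)] <- unname(extra)
  base <- unique(c(.lemma_base, unlist(irregular, use.names = FALSE)))
  vapply(tokens, .lemma_one, character(1),
         irregular = irregular, base = base, USE.NAMES = FALSE)
}
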