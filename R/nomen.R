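# Deterministic gene-symbol assignment following community (sNCGGa-style)
# nomenclature: conserved prior symbols, Arabidopsis-ortholog symbols,
# subfamily serials for MIKC-C genes, and subclass+clade serials
# (MADSD / MADS1A / MADS1G) for MIKC* and type I genes.

SUBCLASS_PREFIX <- c(MIKC_STAR = "MADSD", M_ALPHA = "MADS1A",
                     M_GAMMA = "MADS1G")

# serial letters: a..z, then aa, ab, ...
serial_letter <- function(i) {
  stopifnot(i >= 1)
  if (i <= 26L) return(letters[i])
  paste0(letters[(i - 1L) %/% 26L], letters[(i - 1L) %% 26L + 1L])
}

#' Assign gene symbols to a family catalog
#'
#' Rule precedence per locus: a prior symbol that fits the recommendations is
#' conserved (`kept_existing`; dot-number serials such as `VviSOC1.1` are
#' converted to letter serials, `VviSOC1a`); otherwise the Arabidopsis
#' ortholog's symbol is adopted with the species prefix
#' (`arabidopsis_ortholog`); otherwise MIKC-C loci get subfamily serials
#' (`VviSVPa` style, `subfamily_serial`) and MIKC* / type I loci get
#' subclass+clade serials (`MADSD2a` style, `subclass_clade_serial`,
#' unprefixed). Serial letters follow genomic order (chromosome, then
#' start), which makes assignment deterministic.
#'
#' @param catalog data.frame with columns `locus_id`, `subclass` (one of
#'   `MIKC_C`, `MIKC_STAR`, `M_ALPHA`, `M_GAMMA`), `clade` (integer; required
#'   for MIKC* and type I loci), `chromosome`, `start`, and optionally
#'   `subfamily` (MIKC-C), `prior_symbol`, `at_ortholog`.
#' @param species_prefix e.g. `"Vvi"`.
#' @return data.frame of symbol assignments: `locus_id`, `symbol`,
#'   `rule_used`, `subclass`, `clade`, `serial`.
#' @export
assign_symbols <- function(catalog, species_prefix = "Vvi") {
  req <- c("locus_id", "subclass", "chromosome", "start")
  if (!all(req %in% names(catalog))) {
    stop("catalog must have columns: ", paste(req, collapse = ", "))
  }
  cat_ <- catalog
  for (opt in c("subfamily", "prior_symbol", "at_ortholog", "clade")) {
    if (!opt %in% names(cat_)) cat_[[opt]] <- NA
  }
  bad <- !cat_$subclass %in% c("MIKC_C", names(SUBCLASS_PREFIX))
  if (any(bad)) stop("unknown subclass: ", paste(unique(cat_$subclass[bad]), collapse = ", "))
  need_clade <- cat_$subclass %in% names(SUBCLASS_PREFIX)
  if (any(need_clade & is.na(cat_$clade))) {
    stop("clade index required for MIKC* and type I loci")
  }
  priors <- cat_$prior_symbol[!is.na(cat_$prior_symbol)]
  if (anyDuplicated(priors)) {
    dup <- unique(priors[duplicated(priors)])
    stop("conflict: duplicate prior symbols ", paste(dup, collapse = ", "),
         " on loci ",
         paste(cat_$locus_id[cat_$prior_symbol %in% dup], collapse = ", "))
  }
  ord <- order(cat_$chromosome, cat_$start)
  cat_ <- cat_[ord, , drop = FALSE]

  symbol <- rep(NA_character_, nrow(cat_))
  rule <- rep(NA_character_, nrow(cat_))
  serial <- rep(NA_character_, nrow(cat_))

  fits <- function(s) grepl("^[A-Za-z][A-Za-z0-9]*[a-z]$", s) && !grepl("\\.", s)
  for (i in seq_len(nrow(cat_))) {
    p <- cat_$prior_symbol[i]
    if (!is.na(p)) {
      if (fits(p)) {
        symbol[i] <- p
      } else if (grepl("^(.*?)\\.(\\d+)$", p)) {
        mm <- regmatches(p, regexec("^(.*?)\\.(\\d+)$", p))[[1]]
        symbol[i] <- paste0(mm[2], serial_letter(as.integer(mm[3])))
      } else {
        symbol[i] <- p
      }
      rule[i] <- "kept_existing"
    }
  }
  at_free <- is.na(symbol) & !is.na(cat_$at_ortholog)
  if (any(at_free)) {
    for (i in which(at_free)) {
      symbol[i] <- paste0(species_prefix, cat_$at_ortholog[i])
      rule[i] <- "arabidopsis_ortholog"
    }
    # disambiguate repeated ortholog symbols with genomic-order serials
    dup_sym <- names(which(table(symbol[at_free]) > 1))
    for (s in dup_sym) {
      ii <- which(symbol == s & at_free)
      for (k in seq_along(ii)) {
        serial[ii[k]] <- serial_letter(k)
        symbol[ii[k]] <- paste0(s, serial_letter(k))
      }
    }
  }
  todo <- which(is.na(symbol) & cat_$subclass == "MIKC_C")
  if (length(todo)) {
    if (any(is.na(cat_$subfamily[todo]))) {
      stop("subfamily required for serial naming of MIKC_C loci")
    }
    for (sf in unique(cat_$subfamily[todo])) {
      ii <- todo[cat_$subfamily[todo] == sf]
      for (k in seq_along(ii)) {
        serial[ii[k]] <- serial_letter(k)
        symbol[ii[k]] <- paste0(species_prefix, sf, serial_letter(k))
        rule[ii[k]] <- "subfamily_serial"
      }
    }
  }
  todo <- which(is.na(symbol))
  if (length(todo)) {
    key <- paste(cat_$subclass[todo], cat_$clade[todo])
    for (kk in unique(key)) {
      ii <- todo[key == kk]
      prefix <- SUBCLASS_PREFIX[[cat_$subclass[ii[1]]]]
      for (k in seq_along(ii)) {
        serial[ii[k]] <- serial_letter(k)
        symbol[ii[k]] <- paste0(prefix, cat_$clade[ii[k]], serial_letter(k))
        rule[ii[k]] <- "subclass_clade_serial"
      }
    }
  }
  if (anyDuplicated(symbol)) {
    stop("conflict: assignment produced duplicate symbols ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  }
  out <- data.frame(locus_id = cat_$locus_id, symbol = symbol,
                    rule_used = rule, subclass = cat_$subclass,
                    clade = cat_$clade, serial = serial,
                    stringsAsFactors = FALSE)
  out[match(catalog$locus_id, out$locus_id), , drop = FALSE]
}

#' Parse a gene symbol
#'
#' Inverse of [assign_symbols()] for subclass+clade serial symbols; other
#' prefixed symbols are reported as subfamily records, anything else as
#' `unparsed`.
#'
#' @param symbol character vector of symbols.
#' @return data.frame `symbol`, `kind` (`subclass_clade` / `subfamily` /
#'   `unparsed`), `subclass`, `clade`, `serial`, `subfamily`.
#' @export
parse_symbol <- function(symbol) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(symbol = s, kind = "unparsed", subclass = NA,
                        clade = NA_integer_, serial = NA, subfamily = NA))
    }
    for (sub in names(SUBCLASS_PREFIX)) {
      pat <- sprintf("^%s(\\d+)([a-z]+)$", SUBCLASS_PREFIX[[sub]])
      if (grepl(pat, s)) {
        mm <- regmatches(s, regexec(pat, s))[[1]]
        return(data.frame(symbol = s, kind = "subclass_clade",
                          subclass = sub, clade = as.integer(mm[2]),
                          serial = mm[3], subfamily = NA,
                          stringsAsFactors = FALSE))
      }
    }
    if (grepl("^[A-Z][a-z]{2}[A-Za-z0-9]+$", s)) {
      mm <- regmatches(s, regexec("^([A-Z][a-z]{2})([A-Za-z0-9]*?)([a-z]?)$", s))[[1]]
      return(data.frame(symbol = s, kind = "subfamily", subclass = "MIKC_C",
                        clade = NA_integer_,
                        serial = if (nzchar(mm[4])) mm[4] else NA,
                        subfamily = mm[3], stringsAsFactors = FALSE))
    }
    data.frame(symbol = s, kind = "unparsed", subclass = NA,
               clade = NA_integer_, serial = NA, subfamily = NA)
  }
  do.call(rbind, lapply(symbol, one))
}
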