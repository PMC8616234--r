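# Fusion-call triage: whitelist / known-fusion / read-support filtering,
# support fractions, and subtype assignment by highest support fraction.

#' Default fusion rule set
#'
#' An illustrative, user-overridable rule set: a whitelist of ALL-relevant
#' genes, known recurrent BCP-ALL fusion pairs, and a subtype map covering
#' both orientation-sensitive pairs (\emph{P2RY8-CRLF2}), unordered pairs
#' (\emph{ETV6-RUNX1}, \emph{BCR-ABL1}, ...) and single-partner classes (any
#' \emph{ZNF384}, \emph{NUTM1}, \emph{KMT2A}, \emph{PAX5} or \emph{DUX4}
#' fusion).
#'
#' @return A \linkS4class{FusionRuleSet}.
#' @examples
#' defaultFusionRules()
#' @export
defaultFusionRules <- function() {
    whitelist <- c("ETV6", "RUNX1", "BCR", "ABL1", "ABL2", "KMT2A", "PAX5",
                   "ZNF384", "NUTM1", "DUX4", "CRLF2", "P2RY8", "TCF3",
                   "PBX1", "HLF", "MEF2D", "BCL9", "EBF1", "PDGFRB",
                   "IKZF1", "EPOR", "JAK2", "CSF1R", "IGH", "MLLT1",
                   "MLLT3", "USP2")
    known <- c("ETV6+RUNX1", "ABL1+BCR", "PBX1+TCF3", "HLF+TCF3",
               "BCL9+MEF2D", "EBF1+PDGFRB", "CRLF2+P2RY8", "EPOR+IGH",
               "KMT2A+MLLT1", "KMT2A+MLLT3", "KMT2A+USP2")
    subtypeMap <- c(
        "ETV6+RUNX1" = "ETV6-RUNX1",
        "BCR+ABL1" = "BCR-ABL1",
        "TCF3+PBX1" = "TCF3-PBX1",
        "TCF3+HLF" = "TCF3-HLF",
        "MEF2D+BCL9" = "MEF2D-BCL9",
        "EBF1+PDGFRB" = "EBF1-PDGFRB",
        "P2RY8>CRLF2" = "P2RY8-CRLF2",
        "IGH+EPOR" = "IGH-EPOR",
        "ZNF384" = "ZNF384-r",
        "NUTM1" = "NUTM1-r",
        "KMT2A" = "KMT2A-r",
        "PAX5" = "PAX5 alt",
        "DUX4" = "DUX4-r"
    )
    fusionRuleSet(whitelist = whitelist, knownFusions = known,
                  subtypeMap = subtypeMap)
}

.fusionRequiredCols <- c("sample_id", "gene5", "gene3", "split_reads",
                         "spanning_reads")

#' Read an Arriba-style fusion call table
#'
#' Tab-separated with header columns \code{sample_id, gene5, gene3,
#' breakpoint5, breakpoint3, split_reads, spanning_reads}.
#'
#' @param path File path.
#' @return data.frame of fusion calls.
#' @export
readFusionCalls <- function(path) {
    calls <- read.delim(path, stringsAsFactors = FALSE)
    .requireColumns(calls, .fusionRequiredCols, "fusion call table")
    calls
}

#' Filter fusion calls against a rule set
#'
#' A call is retained iff one of its partners is in the whitelist, or it has
#' strictly more supporting reads (split + spanning) than the non-whitelist
#' threshold (default: more than 10) \emph{and} its unordered gene pair is a
#' known fusion. Dropped calls carry the first violated rule:
#' \code{insufficient_support} (non-whitelist, at or below the read
#' threshold), then \code{not_known_fusion}.
#'
#' @param calls data.frame of fusion calls (see [readFusionCalls()] for
#'   required columns).
#' @param rules A \linkS4class{FusionRuleSet}.
#' @return A list with \code{retained} (subset of \code{calls}) and
#'   \code{dropped} (the complement, with a \code{drop_reason} column).
#' @examples
#' calls <- data.frame(sample_id = "S1", gene5 = c("ETV6", "AAA"),
#'                     gene3 = c("RUNX1", "BBB"),
#'                     split_reads = c(2L, 4L), spanning_reads = c(1L, 4L))
#' filterFusions(calls, defaultFusionRules())$retained$gene5
#' @export
filterFusions <- function(calls, rules = defaultFusionRules()) {
    stopifnot(is(rules, "FusionRuleSet"))
    .requireColumns(calls, .fusionRequiredCols, "fusion call table")
    if (!nrow(calls))
        return(list(retained = calls,
                    dropped = cbind(calls,
                                    drop_reason = character(0))))
    supporting <- calls$split_reads + calls$spanning_reads
    onWhitelist <- calls$gene5 %in% rules@whitelist |
        calls$gene3 %in% rules@whitelist
    enoughSupport <- supporting >= rules@minSupportNonWhitelist
    known <- .pairKey(calls$gene5, calls$gene3) %in% rules@knownFusions
    keep <- onWhitelist | (enoughSupport & known)
    reason <- rep(NA_character_, nrow(calls))
    reason[!keep & !enoughSupport] <- "insufficient_support"
    reason[!keep & enoughSupport & !known] <- "not_known_fusion"
    dropped <- calls[!keep, , drop = FALSE]
    dropped$drop_reason <- reason[!keep]
    list(retained = calls[keep, , drop = FALSE], dropped = dropped)
}

#' Per-call support fraction within a sample
#'
#' The fraction of a sample's total supporting reads (over its retained
#' calls) carried by each call. Fractions within a sample sum to 1.
#'
#' @param retained data.frame of retained fusion calls.
#' @return Numeric vector aligned with the rows of \code{retained}.
#' @examples
#' calls <- data.frame(sample_id = "S1", gene5 = c("A", "B"),
#'                     gene3 = c("C", "D"),
#'                     split_reads = c(20L, 50L), spanning_reads = c(10L, 20L))
#' supportFraction(calls)  # 0.3, 0.7
#' @export
supportFraction <- function(retained) {
    .requireColumns(retained, .fusionRequiredCols, "retained call table")
    supporting <- retained$split_reads + retained$spanning_reads
    totals <- tapply(supporting, retained$sample_id, sum)
    as.numeric(supporting / totals[retained$sample_id])
}

# resolve the subtype-map label for each call; ordered pair keys ("A>B")
# take precedence over unordered ("A+B"), then single-partner keys
.matchSubtype <- function(calls, rules) {
    map <- rules@subtypeMap
    keys <- names(map)
    ordered <- map[grepl(">", keys, fixed = TRUE)]
    unordered <- map[grepl("+", keys, fixed = TRUE)]
    single <- map[!grepl("[>+]", keys)]
    names(unordered) <- vapply(strsplit(names(unordered), "[+]"),
                               function(p) paste(sort(p), collapse = "+"),
                               character(1))
    lab <- rep(NA_character_, nrow(calls))
    okey <- paste(calls$gene5, calls$gene3, sep = ">")
    hit <- okey %in% names(ordered)
    lab[hit] <- unname(ordered[okey[hit]])
    ukey <- .pairKey(calls$gene5, calls$gene3)
    hit <- is.na(lab) & ukey %in% names(unordered)
    lab[hit] <- unname(unordered[ukey[hit]])
    if (length(single)) {
        for (g in sort(names(single))) {
            hit <- is.na(lab) & (calls$gene5 == g | calls$gene3 == g)
            lab[hit] <- unname(single[g])
        }
    }
    lab
}

#' Classify samples by their retained fusion calls
#'
#' Among a sample's retained calls that resolve to a subtype label, the call
#' with the highest support fraction wins; ties break by higher absolute
#' supporting reads, then lexicographically by gene pair. Samples with no
#' label-resolving call get subtype \code{NA}.
#'
#' @param retained data.frame of retained fusion calls (apply
#'   [filterFusions()] first).
#' @param rules A \linkS4class{FusionRuleSet} with a subtype map.
#' @return data.frame with one row per sample present in \code{retained}:
#'   \code{sample_id}, \code{subtype}, \code{gene5}, \code{gene3},
#'   \code{supporting_reads}, \code{support_fraction}.
#' @export
classifyByFusion <- function(retained, rules = defaultFusionRules()) {
    stopifnot(is(rules, "FusionRuleSet"))
    .requireColumns(retained, .fusionRequiredCols, "retained call table")
    samples <- sort(unique(retained$sample_id))
    if (!nrow(retained))
        return(data.frame(sample_id = character(), subtype = character(),
                          gene5 = character(), gene3 = character(),
                          supporting_reads = integer(),
                          support_fraction = numeric(),
                          stringsAsFactors = FALSE))
    frac <- supportFraction(retained)
    lab <- .matchSubtype(retained, rules)
    out <- lapply(samples, function(sid) {
        i <- which(retained$sample_id == sid & !is.na(lab))
        if (!length(i))
            return(data.frame(sample_id = sid, subtype = NA_character_,
                              gene5 = NA_character_, gene3 = NA_character_,
                              supporting_reads = NA_integer_,
                              support_fraction = NA_real_,
                              stringsAsFactors = FALSE))
        supp <- retained$split_reads[i] + retained$spanning_reads[i]
        pair <- paste(retained$gene5[i], retained$gene3[i])
        ord <- order(-frac[i], -supp, pair)
        w <- i[ord[1]]
        data.frame(sample_id = sid, subtype = lab[w],
                   gene5 = retained$gene5[w], gene3 = retained$gene3[w],
                   supporting_reads = retained$split_reads[w] +
                       retained$spanning_reads[w],
                   support_fraction = frac[w], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
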