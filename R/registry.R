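# Gene catalogs, name dialects and canonicalization.
#
# Canonical form is the Adaptive style (TCRBV05-01) since the primary input
# is ImmunoSEQ exports; IMGT-style names (TRBV5-1) resolve through aliases.

#' Construct a gene registry
#'
#' @param vGenes,jGenes ordered character vectors of canonical gene names;
#'   their lengths fix the one-hot encoding dimensions.
#' @param aliases named character vector mapping dialect spellings to
#'   canonical names. IMGT-style aliases for Adaptive-style names are added
#'   automatically.
#' @param blacklist genes whose records [filterRepertoire()] excludes.
#' @return a \linkS4class{GeneRegistry}.
#' @examples
#' reg <- defaultGeneRegistry()
#' length(vGenes(reg))  # 67
#' canonicalizeGene("TRBV5-1*01", reg)
#' @export
geneRegistry <- function(vGenes, jGenes, aliases = character(),
                         blacklist = c("TCRBJ02-05", "TCRBJ02-07")) {
  auto <- autoAliases(c(vGenes, jGenes))
  aliases <- c(aliases, auto[!names(auto) %in% names(aliases)])
  methods::new("GeneRegistry", vGenes = vGenes, jGenes = jGenes,
               aliases = aliases, blacklist = blacklist)
}

# IMGT-style spellings (TRBV5-1) for Adaptive-style canonical names.
autoAliases <- function(genes) {
  m <- regmatches(genes, regexec("^TCRB([VJ])([0-9A-B]+)-([0-9]+)$", genes))
  out <- character()
  for (i in seq_along(genes)) {
    g <- m[[i]]
    if (length(g) == 4L) {
      fam <- sub("^0+", "", g[3]); mem <- sub("^0+", "", g[4])
      out[paste0("TRB", g[2], fam, "-", mem)] <- genes[i]
      if (mem == "1") out[paste0("TRB", g[2], fam)] <- genes[i]
    }
  }
  out
}

#' Default human TCR beta gene registry (67 V, 13 J)
#'
#' The J catalog is the complete Adaptive TCRBJ set (families 1 and 2).
#' The V catalog is a 67-name Adaptive-style list with the usual
#' family/member structure; swap in your own catalog via [geneRegistry()]
#' if your pipeline reports a different gene set.
#'
#' @return a \linkS4class{GeneRegistry}.
#' @export
defaultGeneRegistry <- function() {
  memberCounts <- c("01" = 1, "02" = 1, "03" = 2, "04" = 3, "05" = 8,
                    "06" = 9, "07" = 9, "08" = 2, "09" = 1, "10" = 3,
                    "11" = 3, "12" = 5, "13" = 1, "14" = 1, "15" = 1,
                    "16" = 1, "17" = 1, "18" = 1, "19" = 1, "20" = 1,
                    "21" = 1, "22" = 1, "23" = 1, "24" = 1, "25" = 1,
                    "26" = 1, "27" = 1, "28" = 1, "29" = 1, "30" = 1)
  v <- unlist(lapply(names(memberCounts), function(fam) {
    sprintf("TCRBV%s-%02d", fam, seq_len(memberCounts[[fam]]))
  }))
  v <- c(v, "TCRBVA-01", "TCRBVB-01")  # orphons
  j <- c(sprintf("TCRBJ01-%02d", 1:6), sprintf("TCRBJ02-%02d", 1:7))
  geneRegistry(v, j)
}

#' Canonicalize a gene name
#'
#' Strips allele suffixes (`*01`), resolves dialect aliases (IMGT
#' `TRBV5-1` to Adaptive `TCRBV05-01`), and resolves family-only calls when
#' the family has a single member. Ambiguous calls (empty, `unresolved`,
#' multi-gene `A/B` calls, families with several members) return `NA`
#' rather than raising, so the filter step can tally them.
#'
#' @param x character vector of gene names as reported by a pipeline.
#' @param registry a \linkS4class{GeneRegistry}.
#' @return character vector of canonical names, `NA` where unresolvable.
#' @export
canonicalizeGene <- function(x, registry) {
  stopifnot(methods::is(registry, "GeneRegistry"))
  catalog <- c(registry@vGenes, registry@jGenes)
  vapply(x, function(g) {
    if (is.na(g)) return(NA_character_)
    g <- sub("\\*.*$", "", trimws(g))
    if (g == "" || grepl("unresolved|unknown|undefined", g, ignore.case = TRUE)) {
      return(NA_character_)
    }
    if (grepl("/", g, fixed = TRUE) || grepl(",", g, fixed = TRUE)) {
      return(NA_character_)  # multi-gene call is ambiguous
    }
    if (g %in% catalog) return(g)
    if (g %in% names(registry@aliases)) return(unname(registry@aliases[[g]]))
    # Adaptive family-only call, e.g. TCRBV12: unique-member families resolve
    hit <- regmatches(g, regexec("^TCRB([VJ])([0-9A-B]+)$", g))[[1]]
    if (length(hit) == 3L) {
      members <- grep(sprintf("^TCRB%s%s-", hit[2], hit[3]), catalog, value = TRUE)
      if (length(members) == 1L) return(members)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
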