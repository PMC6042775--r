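# Packaged reference matrix: the published profile-map analysis of the
# Aphra Behn corpus (16 verified plays + 5 questioned works, 13 cluster
# scores and a grand median score per work).

TABLE7_MD5 <- "1a9f2ce32fd50466f4f7df369dbaaa18"

#' Names of the 13 default clusters
#'
#' @return Character vector, in scheme order.
#' @export
cluster_names <- function() {
  names(default_cluster_scheme())
}

#' Load the packaged Behn reference score matrix
#'
#' Returns the published 21-work score matrix (16 verified Behn plays and 5
#' questioned works): 13 per-cluster distance scores and the grand (median)
#' score per work, at the 2-decimal precision of the published analysis.
#' On load the file checksum is verified and the defining invariant is
#' revalidated: every row's grand score must equal the median of its 13
#' cluster scores, and the verified-play grand scores must reproduce the
#' published mean 48.56 and SD 16.41.
#'
#' @return Data frame of class `table7_fixture` with columns `author`
#'   (`"Behn"` or `"Questioned"`), `title`, `grand_score` and the 13
#'   cluster score columns.
#' @examples
#' tab <- load_table7_fixture()
#' subset(tab, author == "Questioned")$title
#' @export
load_table7_fixture <- function() {
  path <- system.file("extdata", "table7_mpm_scores.csv", package = "mpmap")
  if (!nzchar(path)) stop("fixture file not found", call. = FALSE)
  if (!identical(unname(tools::md5sum(path)), TABLE7_MD5)) {
    stop("fixture corruption: checksum mismatch for ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) != 21) {
    stop("fixture corruption: expected 21 rows, found ", nrow(tab),
         call. = FALSE)
  }
  S <- as.matrix(tab[, cluster_names()])
  med <- apply(S, 1, stats::median)
  if (any(abs(med - tab$grand_score) > 1e-9)) {
    bad <- tab$title[abs(med - tab$grand_score) > 1e-9]
    stop("fixture corruption: grand score is not the median of the 13 ",
         "cluster scores for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  behn <- tab$grand_score[tab$author == "Behn"]
  if (length(behn) != 16 ||
      round(mean(behn), 2) != 48.56 || round(stats::sd(behn), 2) != 16.41) {
    stop("fixture corruption: verified-play grand-score mean/SD do not ",
         "match the published 48.56 / 16.41", call. = FALSE)
  }
  class(tab) <- c("table7_fixture", "data.frame")
  tab
}
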