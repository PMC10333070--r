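#' The 26-gene RNA modification "writer" panel
#'
#' Returns the panel of 26 enzymes that deposit or effect the four RNA
#' modification types analysed by the package: seven m6A methyltransferase
#' complex members, four m1A methyltransferases, twelve alternative
#' polyadenylation (APA) 3'-end processing factors, and the three A-to-I
#' editing deaminases.
#'
#' @return A tibble with columns `gene_symbol` (character, uppercase HGNC
#'   symbols) and `mod_class` (factor with levels `m6A`, `m1A`, `APA`,
#'   `AtoI`). Exactly 26 rows, no duplicated symbols.
#'
#' @examples
#' writer_registry()
#' dplyr::count(writer_registry(), mod_class)
#' @export
writer_registry <- function() {
  entries <- list(
    m6A  = c("METTL3", "METTL14", "WTAP", "RBM15", "RBM15B", "ZC3H13",
             "KIAA1429"),
    m1A  = c("TRMT61A", "TRMT61B", "TRMT10C", "TRMT6"),
    APA  = c("CPSF1", "CPSF2", "CPSF3", "CPSF4", "CSTF1", "CSTF2", "CSTF3",
             "PCF11", "CFI", "CLP1", "NUDT21", "PABPN1"),
    AtoI = c("ADAR", "ADARB1", "ADARB2")
  )
  tibble::tibble(
    gene_symbol = unlist(entries, use.names = FALSE),
    mod_class   = factor(rep(names(entries), lengths(entries)),
                         levels = names(entries))
  )
}

#' @rdname writer_registry
#' @export
writer_genes <- function() writer_registry()$gene_symbol
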