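#' Number of genes in an object
#' @param x object
#' @return integer count
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Species labels present in an object
#' @param x object
#' @return character vector of species labels
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Species of each gene
#' @param x object
#' @return named character vector, canonical gene name -> species label
#' @export
setGeneric("geneSpecies", function(x) standardGeneric("geneSpecies"))

#' Gene table of a catalog
#' @param x object
#' @return data.frame of gene records
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' Blocks of a collinearity set
#' @param x object
#' @return list of block records
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' Group membership list
#' @param x object
#' @return named list of groups
#' @export
setGeneric("groupList", function(x) standardGeneric("groupList"))

#' Tether containing each query gene
#' @param x a [TetherSets-class] object
#' @param genes character vector of canonical gene names
#' @return character vector of tether ids, `NA` where a gene is untethered
#'   (not in any orthogroup, or its species was ploidy-excluded)
#' @export
setGeneric("tetherOf", function(x, genes) standardGeneric("tetherOf"))
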