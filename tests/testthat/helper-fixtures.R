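# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

bb_h4 <- function() fixture("h4", function() histone_backbone("H4"))
bb_h3 <- function() fixture("h3", function() histone_backbone("H3.2"))
space_h4 <- function() fixture("sp4", function() enumerate_proteoforms(bb_h4()))
space_h3 <- function() fixture("sp3", function() enumerate_proteoforms(bb_h3()))

# the worked toy table used across the algebra tests
toy_h4_table <- function(replicate = "r1") {
  tibble::tibble(
    proteoform = c("<K20me2>", "<K16acK20me2>", "<K20me3>", "<un>"),
    abundance = c(40, 25, 20, 15),
    replicate = replicate
  )
}

# random valid proteoform on a backbone: each variable site independently
# unmodified or one allowed kind
random_proteoform <- function(backbone) {
  sites <- backbone$sites[backbone$sites$site > 0 |
                            !backbone$n_term_ac_fixed, ]
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    kinds <- c(NA_character_, sites$kinds[[i]])
    k <- sample(kinds, 1)
    if (is.na(k)) return(tibble::tibble())
    tibble::tibble(site = sites$site[i], kind = k)
  })
  proteoform(backbone, rows)
}
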