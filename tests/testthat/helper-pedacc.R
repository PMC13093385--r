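# Shared fixture builders; everything is generated in code at test time.

# wrap a bare parentage table into an offspring_sample
make_sample <- function(mother, father, n_females = max(mother),
                        n_males = max(father) - n_females) {
  structure(
    list(records = data.frame(offspring_id = seq_along(mother),
                              mother_id = as.integer(mother),
                              father_id = as.integer(father)),
         n_obs = length(mother),
         n_females = as.integer(n_females), n_males = as.integer(n_males),
         true_n_p = as.integer(n_females) + as.integer(n_males),
         max_parent_id = max(as.integer(n_females) + as.integer(n_males),
                             mother, father),
         novel_sex = NULL),
    class = "offspring_sample"
  )
}

# fast end-to-end sample from a small cohort (low fecundity keeps it cheap)
small_pipeline_sample <- function(n_p = 10, n_obs = 20, seed = 1,
                                  fecundity = c(30, 60)) {
  ss <- split_sexes(n_p)
  ped <- simulate_breeding(
    breeding_scenario(ss[1], ss[2], fecundity = fecundity), seed = seed)
  sample_offspring(ped, n_obs, seed = seed + 1)
}

n_det_of <- function(sample) {
  length(unique(c(sample$records$mother_id, sample$records$father_id)))
}
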