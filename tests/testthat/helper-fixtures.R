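# Shared fixtures. Heavier objects (simulated repertoires, trained models)
# are built once per test run and cached here; sizes are scaled down from the
# acceptance benchmark to keep module tests fast.

.fixtures <- new.env(parent = emptyenv())

cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a small hand-built heavy sequence touching every region
toy_heavy <- function(id = "toy") {
  pos <- c("1", "2", "23", "30", "40", "57", "70", "104", "106", "120")
  res <- c("E", "V", "C", "G", "L", "S", "A", "C", "R", "W")
  numbered_sequence(id, "heavy", pos, res)
}

species_of <- function(seqs) vapply(seqs, function(s) s$species, "")
vgene_of <- function(seqs) vapply(seqs, function(s) s$v_gene, "")

# small benchmark: heavy repertoire + three calibrated V-gene models
small_heavy_bench <- function() {
  cache("small_heavy", {
    reps <- simulate_repertoire(sim_config(n_per_class = 300, seed = 101))
    is_h <- species_of(reps) == "human"
    vg <- vgene_of(reps)
    labels <- as.integer(is_h)
    parts <- split_dataset(labels, seed = 7)
    neg_train <- reps[parts$train][labels[parts$train] == 0L]
    models <- lapply(c("V1", "V3", "V4"), function(g) {
      pos_train <- reps[parts$train][labels[parts$train] == 1L &
                                     vg[parts$train] == g]
      m <- train_model(pos_train, neg_train, n_estimators = 60, seed = 7,
                       v_gene = g)
      val <- parts$validation
      calibrate_threshold(m, reps[val],
                          as.integer(is_h[val] & vg[val] == g))
    })
    names(models) <- c("V1", "V3", "V4")
    list(reps = reps, is_human = is_h, v_gene = vg, parts = parts,
         models = models)
  })
}

small_light_bench <- function() {
  cache("small_light", {
    kap <- simulate_repertoire(sim_config(n_per_class = 150, chain = "kappa",
                                          seed = 102))
    lam <- simulate_repertoire(sim_config(n_per_class = 150,
                                          chain = "lambda", seed = 103))
    k_h <- kap[species_of(kap) == "human"]
    l_h <- lam[species_of(lam) == "human"]
    ct <- train_chain_type_model(k_h[1:100], l_h[1:100], n_estimators = 40,
                                 seed = 5)
    mk <- train_model(k_h[1:100], kap[species_of(kap) != "human"][1:100],
                      n_estimators = 40, seed = 5, v_gene = "KV1")
    mk <- calibrate_threshold(
      mk, c(k_h[101:130], kap[species_of(kap) != "human"][101:130]),
      c(rep(1L, 30), rep(0L, 30)))
    list(kappa = kap, lambda = lam, chain_type = ct, kappa_model = mk,
         kappa_holdout = k_h[131:140], lambda_holdout = l_h[101:110])
  })
}
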