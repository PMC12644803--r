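# Shared simulated fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

cfg_std <- function() fixture("cfg", game_config)

# Mixed-strategy dyad (FST around 0.4), default human-like noise.
mixed_session <- function() fixture("mixed", function() {
  p <- policy_params(w = 0.55, speed_factor = 0.85, reaction_delay = 0.15,
                     reaction_jitter = 0.35, miscoord_p = 0.05)
  simulate_dyad(cfg_std(), p, p, 400, seed = 42)
})

mixed_cycles <- function() fixture("mixed_cycles", function()
  segment_cycles(mixed_session()))

# Invitation-bearing dyad: A invites, B does not (keeps the invitation
# feature identifiable), partner acceptance below 1 so failed invitations
# occur and are typically retried.
invite_session <- function() fixture("invite", function() {
  pa <- policy_params(w = 0.6, placement_mode = "invite", invite_accept = 0.7,
                      reaction_delay = 0.1, reaction_jitter = 0.2)
  pb <- policy_params(w = 0.6, invite_accept = 0.7,
                      reaction_delay = 0.1, reaction_jitter = 0.2,
                      miscoord_p = 0.15)
  simulate_dyad(cfg_std(), pa, pb, 600, seed = 42)
})

invite_cycles <- function() fixture("invite_cycles", function()
  segment_cycles(invite_session()))

invite_design <- function() fixture("invite_design", function()
  build_design(invite_cycles()))

invite_fit <- function() fixture("invite_fit", function()
  suppressWarnings(fit_glm(invite_design())))

invite_labels <- function() fixture("invite_labels", function()
  classify_session(invite_cycles()))

# Noiseless concurrent dyad: shared draws, no delays, no jitter.
clean_session <- function() fixture("clean", function() {
  p <- policy_params(w = 0.5, speed_factor = 1, reaction_delay = 0,
                     reaction_jitter = 0, hover_drift = 0)
  simulate_dyad(cfg_std(), p, p, 300, seed = 7)
})

# Strict turn-taking dyad (fully cooperative).
turntaking_session <- function() fixture("turntaking", function() {
  p <- policy_params(w = 0, turn_taking = TRUE, speed_factor = 1,
                     reaction_delay = 0, reaction_jitter = 0, hover_drift = 0)
  simulate_dyad(cfg_std(), p, p, 200, seed = 7)
})

# The simulated study cohort used by the decomposition and counterfactual
# analyses.
cohort_records <- function() fixture("cohort", function()
  simulate_cohort(cfg_std(), n_dyads = 30, n_cycles = 500, seed = 5))

cohort_model <- function() fixture("cohort_model", function()
  suppressWarnings(fit_counterfactual_model(cohort_records(), cfg_std())))
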