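{
  "factor_name": "sex",
  "outcome_name": "headache persistence",
  "synthesis_mode": "narrative",
  "studies": [
    {
      "study_id": "stanford2008",
      "phase": 1,
      "design": "prospective_cohort",
      "n_participants": 818,
      "n_events": null,
      "n_prognostic_variables": null,
      "outcome_type": "dichotomous",
      "sample_size_justified": false,
      "effects": [
        {
          "measure": "OR",
          "point": 2.6,
          "ci_low": 1.3,
          "ci_high": 5.2,
          "ci_level": 0.95,
          "adjusted": true,
          "n_covariates": 0
        }
      ],
      "rob": {
        "study_participation": "moderate",
        "study_attrition": "moderate",
        "prognostic_factor_measurement": "moderate",
        "outcome_measurement": "moderate",
        "confounding": "low",
        "analysis": "low"
      },
      "indirect_population": false,
      "indirect_factor": false,
      "indirect_outcome": false,
      "uni_vote": "positive",
      "mv_vote": "positive"
    },
    {
      "study_id": "monastero2006",
      "phase": 1,
      "design": "prospective_cohort",
      "n_participants": 818,
      "n_events": null,
      "n_prognostic_variables": null,
      "outcome_type": "dichotomous",
      "sample_size_justified": false,
      "effects": [
        {
          "measure": "OR",
          "point": 2.7,
          "ci_low": 0.95,
          "ci_high": 7.7,
          "ci_level": 0.95,
          "adjusted": true,
          "n_covariates": 0
        }
      ],
      "rob": {
        "study_participation": "moderate",
        "study_attrition": "moderate",
        "prognostic_factor_measurement": "moderate",
        "outcome_measurement": "moderate",
        "confounding": "low",
        "analysis": "low"
      },
      "indirect_population": false,
      "indirect_factor": false,
      "indirect_outcome": false,
      "uni_vote": "null",
      "mv_vote": "null"
    },
    {
      "study_id": "termine2004",
      "phase": 1,
      "design": "prospective_cohort",
      "n_participants": 818,
      "n_events": null,
      "n_prognostic_variables": null,
      "outcome_type": "dichotomous",
      "sample_size_justified": false,
      "effects": [
        {
          "measure": "OR",
          "point": 2.9,
          "ci_low": 0.98,
          "ci_high": 8.6,
          "ci_level": 0.95,
          "adjusted": true,
          "n_covariates": 0
        }
      ],
      "rob": {
        "study_participation": "moderate",
        "study_attrition": "moderate",
        "prognostic_factor_measurement": "moderate",
        "outcome_measurement": "moderate",
        "confounding": "low",
        "analysis": "low"
      },
      "indirect_population": false,
      "indirect_factor": false,
      "indirect_outcome": false,
      "uni_vote": "null",
      "mv_vote": "null"
    },
    {
      "study_id": "wang2007",
      "phase": 1,
      "design": "prospective_cohort",
      "n_participants": 818,
      "n_events": null,
      "n_prognostic_variables": null,
      "outcome_type": "dichotomous",
      "sample_size_justified": false,
      "effects": [
        {
          "measure": "OR",
          "point": 1.2,
          "ci_low": 0.8,
          "ci_high": 1.8,
          "ci_level": 0.95,
          "adjusted": true,
          "n_covariates": 0
        }
      ],
      "rob": {
        "study_participation": "moderate",
        "study_attrition": "moderate",
        "prognostic_factor_measurement": "moderate",
        "outcome_measurement": "moderate",
        "confounding": "low",
        "analysis": "low"
      },
      "indirect_population": false,
      "indirect_factor": false,
      "indirect_outcome": false,
      "uni_vote": null,
      "mv_vote": "null"
    }
  ]
}
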