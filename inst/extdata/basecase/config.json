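{
  "schema": "hfcea/parameters/v1",
  "transitions": {
    "period_breaks": [3, 8],
    "matrices": "transitions.csv"
  },
  "survival": {
    "cv_death": {
      "family": "weibull",
      "coefs": {
        "intercept": 5.603015484419,
        "treatment": 0.0638120725294356,
        "Q1": -0.45,
        "Q2": -0.28,
        "Q3": -0.14
      },
      "ancillary": {
        "sigma": 0.9
      },
      "ref_state": "Q4"
    },
    "all_cause_death": {
      "family": "weibull",
      "coefs": {
        "intercept": 4.35,
        "treatment": 0,
        "Q1": -0.4,
        "Q2": -0.25,
        "Q3": -0.12
      },
      "ancillary": {
        "sigma": 0.95
      },
      "ref_state": "Q4"
    },
    "discontinuation": {
      "family": "gengamma",
      "coefs": {
        "intercept": 4.63456596007677,
        "Q1": -0.15,
        "Q2": -0.08,
        "Q3": -0.04
      },
      "ancillary": {
        "sigma": 1.2,
        "Q": 0.7
      },
      "ref_state": "Q4"
    }
  },
  "hhf": {
    "intercept": -5.25575522675811,
    "treatment_coef": -0.205491013036698,
    "state_coefs": {
      "Q1": 0.641853886172395,
      "Q2": 0.371563556432483,
      "Q3": 0.139761942375159
    },
    "ref_state": "Q4"
  },
  "adverse_events": "adverse_events.csv",
  "costs": {
    "monthly_drug_cost": {
      "EPG_SOC": 212,
      "SOC": 101
    },
    "hhf_cost": 5276,
    "cv_death_cost": 2573,
    "noncv_death_cost": 0,
    "monthly_disease_mgmt_cost": 28,
    "currency_year": 2022
  },
  "utilities": {
    "state_utility": {
      "Q1": 0.613,
      "Q2": 0.707,
      "Q3": 0.778,
      "Q4": 0.832
    },
    "hhf_disutility": -0.335,
    "hhf_disutility_duration": 12
  },
  "economics": {
    "annual_discount_rate_cost": 0.03,
    "annual_discount_rate_benefit": 0.03,
    "cet": 47439,
    "cycle_length": 1,
    "horizon": "lifetime",
    "starting_age": 64.6,
    "half_cycle_correction": true,
    "max_age": 100
  },
  "life_table": {
    "table": "life_table.csv",
    "sex_mix": {
      "male": 0.55,
      "female": 0.45
    }
  },
  "treatment_effect": {
    "hr_hhf_dsa_bounds": {
      "low": 0.6,
      "high": 0.83
    },
    "subgroups": {
      "t2d": {
        "hr_cv": 1.01,
        "hr_hhf": 0.78
      },
      "non_t2d": {
        "hr_cv": 0.83,
        "hr_hhf": 0.77
      }
    }
  },
  "combine": {
    "weight_hfref": 0.67,
    "weight_ef40": 0.33,
    "psa_resample_counts": {
      "hfref": 670,
      "ef40": 330
    },
    "psa_total": 1000
  }
}
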