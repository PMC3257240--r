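{
  "species": [
    {
      "name": "coatA",
      "klass": "coat",
      "radius": 0.02,
      "diffusion_coeff": "stokes_einstein",
      "initial_counts": {
        "cytosol": 60
      }
    },
    {
      "name": "coatB",
      "klass": "coat",
      "radius": 0.02,
      "diffusion_coeff": "stokes_einstein",
      "initial_counts": {
        "cytosol": 60
      }
    },
    {
      "name": "motor1",
      "klass": "motor",
      "radius": 0.01,
      "diffusion_coeff": "stokes_einstein",
      "initial_counts": {
        "cytosol": 30
      },
      "speed": 1,
      "direction": 1
    },
    {
      "name": "motor2",
      "klass": "motor",
      "radius": 0.01,
      "diffusion_coeff": "stokes_einstein",
      "initial_counts": {
        "cytosol": 30
      },
      "speed": 1,
      "direction": -1
    },
    {
      "name": "snareX",
      "klass": "snare",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    },
    {
      "name": "snareY",
      "klass": "snare",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    },
    {
      "name": "snareU",
      "klass": "snare",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    },
    {
      "name": "snareV",
      "klass": "snare",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    },
    {
      "name": "cargo1",
      "klass": "cargo_membrane",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    },
    {
      "name": "cargo2",
      "klass": "cargo_membrane",
      "radius": 0.005,
      "diffusion_coeff": "stokes_einstein"
    }
  ],
  "tables": {
    "k_coat_cargo": {
      "coatA": {
        "cargo1": 5000,
        "cargo2": 0
      },
      "coatB": {
        "cargo1": 0,
        "cargo2": 5000
      }
    },
    "k_coat_snare": {
      "coatA": {
        "snareX": 10000,
        "snareY": 0,
        "snareU": 0,
        "snareV": 2000
      },
      "coatB": {
        "snareX": 2000,
        "snareY": 0,
        "snareU": 0,
        "snareV": 10000
      }
    },
    "k_coat_motor": {
      "coatA": {
        "motor1": 20000,
        "motor2": 0
      },
      "coatB": {
        "motor1": 0,
        "motor2": 20000
      }
    },
    "snare_strength": {
      "snareX": {
        "snareX": 0,
        "snareY": 1,
        "snareU": 0,
        "snareV": 0
      },
      "snareY": {
        "snareX": 1,
        "snareY": 0,
        "snareU": 0,
        "snareV": 0
      },
      "snareU": {
        "snareX": 0,
        "snareY": 0,
        "snareU": 0,
        "snareV": 1
      },
      "snareV": {
        "snareX": 0,
        "snareY": 0,
        "snareU": 1,
        "snareV": 0
      }
    },
    "catcher_rate": {
      "cargo1": {
        "coatA": 10000000,
        "coatB": 0
      },
      "cargo2": {
        "coatA": 0,
        "coatB": 10000000
      }
    },
    "motor_catcher_rate": {
      "cargo1": {
        "motor1": 200000,
        "motor2": 0
      },
      "cargo2": {
        "motor1": 0,
        "motor2": 200000
      }
    },
    "coat_on_off": {
      "coatA": {
        "k_off": 0.08
      },
      "coatB": {
        "k_off": 0.08
      }
    },
    "motor_on_off": {
      "motor1": {
        "k_off": 0.005
      },
      "motor2": {
        "k_off": 0.005
      }
    },
    "k_poly": 0.25,
    "k_fus_pair": 700000000,
    "tau_pair": 2,
    "class_limits": {
      "cargo": 20,
      "snare": 15,
      "motor": 5
    },
    "shell_size": 30,
    "k_fil_bind": 50000000,
    "k_clust": 500000000
  },
  "scenario": {
    "cell": {
      "cell_radius": 2.5,
      "nucleus_radius": 0
    },
    "cytoskeleton_style": "dipole",
    "cytoskeleton_params": {
      "n": 30
    },
    "compartments": [
      {
        "identity": "compartment1",
        "position": [-1.4, 0, 0],
        "radius": 0.4,
        "counts": {
          "cargo1": 400,
          "snareX": 250,
          "snareU": 150,
          "snareY": 100,
          "snareV": 100,
          "motor1": 50,
          "coatA": 60
        }
      },
      {
        "identity": "compartment2",
        "position": [1.4, 0, 0],
        "radius": 0.4,
        "counts": {
          "cargo2": 400,
          "snareV": 250,
          "snareY": 150,
          "snareU": 100,
          "snareX": 100,
          "motor2": 50,
          "coatB": 60
        }
      }
    ],
    "vesicle_radius": 0.05
  },
  "params": {
    "dt": 0.02,
    "reaction_stride": 5,
    "t_end": 60,
    "seed": 1,
    "boost_speed": 0.3,
    "depol_time": 2,
    "depol_lag": 0.5,
    "ref_radius": 0.05,
    "ref_D": 0.1,
    "stall_detach_time": 1
  }
}
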