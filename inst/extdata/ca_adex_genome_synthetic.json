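{
  "parameters": {
    "C_m_s": 150,
    "g_L_s": 10,
    "E_L_s": -70,
    "Delta_T": 2,
    "V_th_s": -54.1039979016345,
    "V_th": -30,
    "V_reset": -54.2824734219213,
    "t_ref": 2,
    "a": 3.46045469618789,
    "b": 80.4779869174709,
    "tau_w": 200.734597320209,
    "g_w": 1,
    "w_BAP": 1800,
    "d_BAP": 1.5,
    "C_m_d": 237.195426523245,
    "g_L_d": 24.4415428496492,
    "E_L_d": -70,
    "g_C": 38.3414801951164,
    "g_Ca": 27.2450741336228,
    "E_Ca": 50,
    "m_slope": -0.29522904841588,
    "m_half": -44.6,
    "h_slope": 0.1,
    "h_half": -23.0559372748186,
    "tau_m_Ca": 67.7775061844209,
    "tau_h_Ca": 197.777480580625,
    "g_K": 12.4603787712413,
    "E_K": -85,
    "tau_m_KCa": 30,
    "Ca_th": 0.00043,
    "const_KCa": 4,
    "phi_Ca": 5.75509633576532e-08,
    "Ca_0": 0.0001,
    "tau_Ca": 118.12859724834,
    "tau_r_beta": 1,
    "tau_d_beta": 9.4
  },
  "bounds": {
    "C_m_s": [100, 400],
    "g_L_s": [5, 30],
    "E_L_s": [-80, -60],
    "Delta_T": [0.5, 5],
    "V_th_s": [-60, -40],
    "V_th": [-40, -20],
    "V_reset": [-65, -50],
    "t_ref": [0, 5],
    "a": [0, 10],
    "b": [0, 250],
    "tau_w": [50, 500],
    "g_w": [0.5, 2],
    "w_BAP": [0, 6000],
    "d_BAP": [0.5, 3],
    "C_m_d": [40, 300],
    "g_L_d": [2, 60],
    "E_L_d": [-80, -60],
    "g_C": [0, 60],
    "g_Ca": [1, 80],
    "E_Ca": [30, 80],
    "m_slope": [-1, -0.05],
    "m_half": [-58, -10],
    "h_slope": [0.02, 0.5],
    "h_half": [-60, -20],
    "tau_m_Ca": [1, 80],
    "tau_h_Ca": [20, 300],
    "g_K": [1, 80],
    "E_K": [-95, -75],
    "tau_m_KCa": [0.5, 30],
    "Ca_th": [0.0001, 0.005],
    "const_KCa": [1, 8],
    "phi_Ca": [1e-08, 1e-05],
    "Ca_0": [1e-05, 0.0005],
    "tau_Ca": [20, 500],
    "tau_r_beta": [0.5, 5],
    "tau_d_beta": [5, 30]
  }
}
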