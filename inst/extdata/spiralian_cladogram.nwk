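((((C_gigas,P_fucata)Bivalvia,((L_gigantea,N_fuscoviridis)Lottiidae,P_vulgata)Gastropoda)Mollusca,((S_lamarcki,S_kraussi)Spirobranchus,((C_teleta,H_robusta)CH,P_dumerilii)CHP)Annelida)Trochozoa,L_anatina)Lophotrochozoa;
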