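dataset,method,subject,accuracy_pct
C3D3a_4C,EFA_LDA_2class,1,52.22
C3D3a_4C,EFA_LDA_2class,2,46.67
C3D3a_4C,EFA_LDA_2class,3,63.33
C3D3a_4C,QR-EFA,1,90.00
C3D3a_4C,QR-EFA,2,93.33
C3D3a_4C,QR-EFA,3,90.83
C4D2a_4C,EFA_LDA_2class,1,53.47
C4D2a_4C,EFA_LDA_2class,2,52.08
C4D2a_4C,EFA_LDA_2class,3,55.55
C4D2a_4C,EFA_LDA_2class,4,55.55
C4D2a_4C,EFA_LDA_2class,5,54.16
C4D2a_4C,EFA_LDA_2class,6,45.13
C4D2a_4C,EFA_LDA_2class,7,58.33
C4D2a_4C,EFA_LDA_2class,8,47.72
C4D2a_4C,EFA_LDA_2class,9,51.38
C4D2a_4C,QR-EFA,1,97.15
C4D2a_4C,QR-EFA,2,97.99
C4D2a_4C,QR-EFA,3,97.05
C4D2a_4C,QR-EFA,4,98.33
C4D2a_4C,QR-EFA,5,98.47
C4D2a_4C,QR-EFA,6,97.85
C4D2a_4C,QR-EFA,7,98.78
C4D2a_4C,QR-EFA,8,97.36
C4D2a_4C,QR-EFA,9,97.81
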