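9.1.18.7
9.10.12.16
9.10.18.9
9.10.23.24
9.10.27.17
9.10.28.23
9.10.29.6
9.10.29.7
9.11.1.13
9.11.11.1
9.11.15.9
9.11.21.6
9.11.27.15
9.11.27.23
9.11.6.25
9.11.7.27
9.12.19.12
9.12.30.20
9.12.4.5
9.12.8.12
9.13.17.30
9.13.6.23
9.14.1.5
9.14.6.10
9.15.28.29
9.15.6.9
9.16.23.22
9.16.24.27
9.16.25.12
9.16.30.26
9.16.30.8
9.17.22.26
9.17.26.10
9.17.30.17
9.18.15.19
9.18.20.8
9.18.23.30
9.19.12.16
9.19.27.11
9.19.27.5
9.2.10.28
9.2.11.25
9.2.17.26
9.2.2.15
9.2.20.18
9.2.29.13
9.2.6.28
9.2.9.11
9.22.12.21
9.25.13.19
9.26.14.26
9.27.29.30
9.28.23.8
9.28.9.29
9.3.11.1
9.3.19.4
9.3.25.21
9.3.25.24
9.3.27.29
9.3.5.25
9.31.29.23
9.32.29.4
9.35.12.17
9.37.4.16
9.4.27.2
9.4.30.8
9.4.4.23
9.5.16.10
9.6.10.8
9.6.15.19
9.6.29.8
9.6.5.15
9.7.16.28
9.7.19.19
9.7.23.26
9.8.27.30
9.8.8.25
9.9.11.26
9.9.20.26
9.9.6.11
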