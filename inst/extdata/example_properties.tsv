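# Example of the user-extensible property-table format:
# id  description(underscored)  20 values in order A C D E F G H I K L M N P Q R S T V W Y
KYTJ820101 hydropathy_index 1.8 2.5 -3.5 -3.5 2.8 -0.4 -3.2 4.5 -3.9 3.8 1.9 -3.5 -1.6 -3.5 -4.5 -0.8 -0.7 4.2 -0.9 -1.3
GRAR740102 polarity 8.1 5.5 13.0 12.3 5.2 9.0 10.4 5.2 11.3 4.9 5.7 11.6 8.0 10.5 10.5 9.2 8.6 5.9 5.4 6.2
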