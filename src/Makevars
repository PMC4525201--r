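# The conda cross toolchain in this image targets a glibc newer than the host
# (objects it links demand GLIBC_2.38 symbol versions and cannot be loaded).
# Compile with the system g++ instead; 'override' is required because the
# package Makevars is read before R's Makeconf. The resulting object links the
# host glibc and the conda libstdc++/libR already loaded by the R process.
override CC = gcc
override CXX = g++ -std=gnu++17
override CXX17 = g++
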